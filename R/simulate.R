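# Forward simulator: an annotated ancestral region is triplicated at the
# whole-genome-triplication (WGT) node and evolved along the species tree
# (((A,C),B), REF) with clock-like codon substitution, sub-genome-biased
# exon deletion, and structural rearrangements.  Every event is logged in a
# truth record for parameter-recovery tests.

SUBGENOMES <- c("LF", "MF1", "MF2")
BRANCHES <- c("stem_ABC", "stem_AC", "term_A", "term_B", "term_C")

#' Evolution parameters
#'
#' Holds the clock and fractionation parameters of the simulator.  Node
#' ages default to the Brassica setting: triplication at 11.6 Mya, B-genome
#' split at 6.2 Mya, A/C split at 3.2 Mya, with synonymous rate
#' `mu = 1.5e-8` substitutions/site/year, so that expected pairwise
#' synonymous divergence between tips separated by time T is `2 mu T`.
#'
#' @param mu synonymous substitution rate per site per year.
#' @param omega acceptance probability of a nonsynonymous change relative
#'   to a synonymous one (default 0.15).
#' @param t_wgt_mya,t_b_split_mya,t_ac_split_mya node ages in Mya; must be
#'   non-increasing in that order.
#' @param exon_del_prob_per_branch per-exon deletion hazard per My of
#'   branch, before the sub-genome bias multiplier.
#' @param subgenome_bias named non-decreasing multipliers for the LF, MF1
#'   and MF2 deletion rates.
#' @param n_inversions,n_tandem_dups,n_foreign_insertions,n_te_insertions
#'   structural event counts per branch: either a single count applied to
#'   every branch or a named vector over
#'   `stem_ABC, stem_AC, term_A, term_B, term_C` (unnamed branches get 0).
#' @param inversion_span_genes number of consecutive genes covered by an
#'   inversion event.
#' @param te_len_bp mean length of a TE-like filler insertion.
#' @param seed integer seed used by [evolve_polyploid_genomes()].
#' @return list of class `evolution_params`.
#' @export
evolution_params <- function(mu = 1.5e-8, omega = 0.15,
                             t_wgt_mya = 11.6, t_b_split_mya = 6.2,
                             t_ac_split_mya = 3.2,
                             exon_del_prob_per_branch = 0.05,
                             subgenome_bias = c(LF = 0.5, MF1 = 1.0, MF2 = 1.3),
                             n_inversions = c(stem_AC = 1),
                             n_tandem_dups = c(term_B = 1),
                             n_foreign_insertions = c(term_A = 1, term_B = 1, term_C = 2),
                             n_te_insertions = c(term_A = 1, term_B = 1, term_C = 3),
                             inversion_span_genes = 5,
                             te_len_bp = 2000,
                             seed = 1L) {
  stopifnot(mu >= 0, omega >= 0, exon_del_prob_per_branch >= 0,
            t_wgt_mya >= t_b_split_mya, t_b_split_mya >= t_ac_split_mya,
            t_ac_split_mya >= 0, length(subgenome_bias) == 3L,
            all(diff(subgenome_bias) >= 0), all(subgenome_bias >= 0),
            inversion_span_genes >= 2, te_len_bp > 0)
  names(subgenome_bias) <- SUBGENOMES
  out <- list(
    mu = mu, omega = omega,
    t_wgt_mya = t_wgt_mya, t_b_split_mya = t_b_split_mya,
    t_ac_split_mya = t_ac_split_mya,
    exon_del_prob_per_branch = exon_del_prob_per_branch,
    subgenome_bias = subgenome_bias,
    n_inversions = per_branch_counts(n_inversions),
    n_tandem_dups = per_branch_counts(n_tandem_dups),
    n_foreign_insertions = per_branch_counts(n_foreign_insertions),
    n_te_insertions = per_branch_counts(n_te_insertions),
    inversion_span_genes = inversion_span_genes,
    te_len_bp = te_len_bp,
    seed = as.integer(seed)
  )
  class(out) <- "evolution_params"
  out
}

# Internal: normalise a scalar or named per-branch event count.
per_branch_counts <- function(x) {
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.integer(x), 5L), BRANCHES))
  }
  out <- stats::setNames(integer(5L), BRANCHES)
  bad <- setdiff(names(x), BRANCHES)
  if (length(bad)) stop("unknown branch name(s): ", paste(bad, collapse = ", "))
  out[names(x)] <- as.integer(x)
  out
}

# Branch lengths (My) implied by the node ages.
branch_lengths <- function(params) {
  c(stem_ABC = params$t_wgt_mya - params$t_b_split_mya,
    stem_AC = params$t_b_split_mya - params$t_ac_split_mya,
    term_A = params$t_ac_split_mya,
    term_B = params$t_b_split_mya,
    term_C = params$t_ac_split_mya)
}

#' Simulate an annotated ancestral genomic region
#'
#' Builds a reference (`REF`) region of `n_genes` protein-coding genes on
#' random strands separated by intergenic spacers.  Every gene's CDS starts
#' with ATG, ends with a stop codon and contains no internal stops; exon
#' lengths are multiples of 3 so that exons tile the CDS on codon
#' boundaries.
#'
#' @param n_genes number of genes (`>= 1`); ids are `g1..gN` in coordinate
#'   order.
#' @param mean_exons_per_gene mean exon count (1 + Poisson).
#' @param mean_exon_len mean exon length in bp (rounded to codons).
#' @param mean_intergenic_len mean intergenic spacer in bp.
#' @param mean_intron_len mean intron length in bp.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return a `genome_copy` (see [assemble_copy()]) with genome and copy
#'   labels `REF`.
#' @export
simulate_ancestral_region <- function(n_genes, mean_exons_per_gene = 3,
                                      mean_exon_len = 150,
                                      mean_intergenic_len = 600,
                                      mean_intron_len = 120,
                                      seed = 1L) {
  if (!isTRUE(n_genes >= 1)) stop("n_genes must be >= 1")
  if (mean_exons_per_gene < 1 || mean_exon_len <= 0 ||
      mean_intergenic_len <= 0 || mean_intron_len <= 0) {
    stop("mean_exons_per_gene, mean_exon_len, mean_intergenic_len and ",
         "mean_intron_len must be positive")
  }
  set.seed(as.integer(seed))
  aa <- codon_aa()
  sense <- which(aa != "*")
  stops <- which(aa == "*")
  atg <- match("ATG", codon_universe())
  rlen <- function(mean) max(1L, as.integer(round(stats::rnorm(1, mean, mean / 5))))
  elements <- list(list(type = "igs", seq = random_dna(rlen(mean_intergenic_len))))
  for (g in seq_len(n_genes)) {
    n_ex <- 1L + stats::rpois(1L, max(0, mean_exons_per_gene - 1))
    mean_codons <- max(2, round(mean_exon_len / 3))
    n_cod <- pmax(2L, stats::rpois(n_ex, mean_codons))
    if (n_ex == 1L) n_cod <- max(n_cod, 3L)
    exon_codons <- lapply(n_cod, function(k) sample(sense, k, replace = TRUE))
    exon_codons[[1L]][1L] <- atg
    last <- length(exon_codons)
    exon_codons[[last]][n_cod[last]] <- sample(stops, 1L)
    introns <- if (n_ex > 1L) {
      vapply(seq_len(n_ex - 1L), function(i) random_dna(rlen(mean_intron_len)), "")
    } else character(0)
    elements[[length(elements) + 1L]] <- list(
      type = "gene", id = paste0("g", g), anc = paste0("g", g),
      strand = sample(c("+", "-"), 1L),
      exon_codons = exon_codons,
      exon_anc = seq_len(n_ex),
      introns = introns,
      foreign = FALSE
    )
    elements[[length(elements) + 1L]] <-
      list(type = "igs", seq = random_dna(rlen(mean_intergenic_len)))
  }
  assemble_copy(elements, genome = "REF", copy = "REF")
}

#' Assemble a genome copy from its internal element list
#'
#' Concatenates the element list (intergenic spacers, TE insertions and
#' gene structures) into a sequence and a coordinate annotation.  Genes on
#' the minus strand are reverse-complemented in place.  Coordinates are
#' 1-based inclusive.
#'
#' @param elements internal element list.
#' @param genome,copy labels (`A`/`B`/`C`/`REF`; `LF`/`MF1`/`MF2`/`REF`).
#' @return list of class `genome_copy`: `genome`, `copy`, `sequence`,
#'   `genes` (data frame `id`, `ancestral_id`, `strand`, `start`, `end`,
#'   `foreign`), `exons` (data frame `gene_id`, `anc_index`, `start`,
#'   `end`), `tes` (data frame `start`, `end`), and the `elements` list.
#' @export
assemble_copy <- function(elements, genome, copy) {
  seq_parts <- character(length(elements))
  pos <- 0L
  g_id <- character(0); g_anc <- character(0); g_strand <- character(0)
  g_start <- integer(0); g_end <- integer(0); g_foreign <- logical(0)
  e_gene <- character(0); e_anc <- integer(0)
  e_start <- integer(0); e_end <- integer(0)
  te_start <- integer(0); te_end <- integer(0)
  for (k in seq_along(elements)) {
    el <- elements[[k]]
    if (el$type == "igs") {
      seq_parts[k] <- el$seq
      pos <- pos + nchar(el$seq)
    } else if (el$type == "te") {
      te_start <- c(te_start, pos + 1L)
      te_end <- c(te_end, pos + nchar(el$seq))
      seq_parts[k] <- el$seq
      pos <- pos + nchar(el$seq)
    } else if (el$type == "gene") {
      ex_seqs <- vapply(el$exon_codons, codons_to_cds, "")
      n_ex <- length(ex_seqs)
      ex_len <- nchar(ex_seqs)
      in_len <- if (n_ex > 1L) nchar(el$introns) else integer(0)
      # interleave exon and intron lengths to get local coordinates
      parts <- character(2L * n_ex - 1L)
      parts[seq(1L, by = 2L, length.out = n_ex)] <- ex_seqs
      if (n_ex > 1L) parts[seq(2L, by = 2L, length.out = n_ex - 1L)] <- el$introns
      steps <- c(rbind(ex_len, c(in_len, 0L)))[seq_len(2L * n_ex - 1L)]
      ends <- cumsum(steps)
      local_end <- ends[seq(1L, by = 2L, length.out = n_ex)]
      local_start <- local_end - ex_len + 1L
      gseq <- paste(parts, collapse = "")
      glen <- nchar(gseq)
      anc_idx <- el$exon_anc
      if (el$strand == "-") {
        gseq <- revcomp(gseq)
        tmp_start <- glen - local_end + 1L
        tmp_end <- glen - local_start + 1L
        ord <- order(tmp_start)
        local_start <- tmp_start[ord]
        local_end <- tmp_end[ord]
        anc_idx <- anc_idx[ord]
      }
      g_id <- c(g_id, el$id)
      g_anc <- c(g_anc, if (is.null(el$anc)) NA_character_ else el$anc)
      g_strand <- c(g_strand, el$strand)
      g_start <- c(g_start, pos + 1L)
      g_end <- c(g_end, pos + glen)
      g_foreign <- c(g_foreign, isTRUE(el$foreign))
      e_gene <- c(e_gene, rep(el$id, n_ex))
      e_anc <- c(e_anc, anc_idx)
      e_start <- c(e_start, pos + local_start)
      e_end <- c(e_end, pos + local_end)
      seq_parts[k] <- gseq
      pos <- pos + glen
    } else {
      stop("unknown element type: ", el$type)
    }
  }
  out <- list(
    genome = genome, copy = copy,
    sequence = paste(seq_parts, collapse = ""),
    genes = data.frame(id = g_id, ancestral_id = g_anc, strand = g_strand,
                       start = g_start, end = g_end, foreign = g_foreign,
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = e_gene, anc_index = e_anc,
                       start = e_start, end = e_end, stringsAsFactors = FALSE),
    tes = data.frame(start = te_start, end = te_end),
    elements = elements
  )
  class(out) <- "genome_copy"
  out
}

#' @export
print.genome_copy <- function(x, ...) {
  cat(sprintf("genome_copy %s/%s: %d bp, %d genes, %d exons, %d TEs\n",
              x$genome, x$copy, nchar(x$sequence), nrow(x$genes),
              nrow(x$exons), nrow(x$tes)))
  invisible(x)
}

# Internal: apply codon substitutions to one gene element over a branch of
# t_years.  Per codon the number of proposed single-nucleotide changes is
# Poisson(3 mu t); a proposal is accepted with probability 1 if synonymous,
# omega if nonsynonymous, 0 if it would create a stop codon.  Stop codons
# (the terminal stop) never mutate.
mutate_gene_codons <- function(exon_codons, mu, t_years, omega) {
  nb <- codon_neighbors()
  aa <- codon_aa()
  lambda <- 3 * mu * t_years
  lapply(exon_codons, function(cod) {
    nev <- stats::rpois(length(cod), lambda)
    for (i in which(nev > 0L)) {
      for (e in seq_len(nev[i])) {
        cur <- cod[i]
        if (aa[cur] == "*") next
        j <- sample.int(9L, 1L)
        type <- nb$type[cur, j]
        if (type == "stop") next
        if (type == "syn" || stats::runif(1) < omega) cod[i] <- nb$idx[cur, j]
      }
    }
    cod
  })
}

# Internal: evolve an element list along one branch for one sub-genome copy.
# `events` is the rearrangement plan rows for this (branch, copy).
# `log_env` accumulates truth entries.
evolve_branch <- function(elements, branch, copy, len_my, params, events, log_env) {
  t_years <- len_my * 1e6
  p_noncoding <- 1 - exp(-params$mu * t_years)
  bias <- params$subgenome_bias[[copy]]
  p_del <- 1 - (1 - min(params$exon_del_prob_per_branch * bias, 1))^len_my
  out <- list()
  for (el in elements) {
    if (el$type %in% c("igs", "te")) {
      el$seq <- mutate_neutral(el$seq, p_noncoding)
      out[[length(out) + 1L]] <- el
      next
    }
    # substitutions
    el$exon_codons <- mutate_gene_codons(el$exon_codons, params$mu, t_years,
                                         params$omega)
    el$introns <- vapply(el$introns, mutate_neutral, "", p_sub = p_noncoding,
                         USE.NAMES = FALSE)
    # exon deletions (ancestral genes only)
    if (!isTRUE(el$foreign) && !is.na(el$anc) && p_del > 0) {
      keep <- stats::runif(length(el$exon_codons)) >= p_del
      if (!all(keep)) {
        for (ix in el$exon_anc[!keep]) {
          log_env$losses[[length(log_env$losses) + 1L]] <- data.frame(
            branch = branch, copy = copy, gene = el$id, exon = ix,
            stringsAsFactors = FALSE)
        }
        el <- delete_exons(el, keep)
      }
    }
    if (is.null(el)) next  # gene fully lost
    out[[length(out) + 1L]] <- el
  }
  apply_rearrangements(out, branch, copy, params, events, log_env)
}

# Internal: drop exons flagged FALSE, merging flanking introns; returns NULL
# when no exon survives (the residual introns are dropped with the gene).
delete_exons <- function(el, keep) {
  if (!any(keep)) return(NULL)
  n <- length(el$exon_codons)
  introns <- el$introns
  # walk from the last exon so intron indices stay valid
  for (i in rev(which(!keep))) {
    if (length(introns)) {
      drop_i <- min(i, length(introns))
      introns <- introns[-drop_i]
    }
  }
  el$exon_codons <- el$exon_codons[keep]
  el$exon_anc <- el$exon_anc[keep]
  el$introns <- introns
  el
}

# Internal: structural events for one (branch, copy).
apply_rearrangements <- function(elements, branch, copy, params, events, log_env) {
  gene_pos <- function(els) which(vapply(els, function(e) e$type == "gene", TRUE))
  for (ev in events) {
    if (ev == "inversion") {
      gp <- gene_pos(elements)
      anc_gp <- gp[vapply(elements[gp], function(e) !isTRUE(e$foreign), TRUE)]
      span <- min(params$inversion_span_genes, length(anc_gp))
      if (span < 2L) next
      s <- sample.int(length(anc_gp) - span + 1L, 1L)
      first <- anc_gp[s]
      last <- anc_gp[s + span - 1L]
      seg <- elements[first:last]
      seg <- rev(lapply(seg, function(e) {
        if (e$type == "gene") {
          # flipping the strand flag is the whole per-gene effect: assembly
          # lays a minus-strand gene out reverse-complemented already
          e$strand <- if (e$strand == "+") "-" else "+"
        } else {
          e$seq <- revcomp(e$seq)
        }
        e
      }))
      genes_in <- vapply(Filter(function(e) e$type == "gene", seg),
                         function(e) e$id, "")
      elements <- c(elements[seq_len(first - 1L)], seg,
                    if (last < length(elements))
                      elements[(last + 1L):length(elements)])
      log_env$rearr[[length(log_env$rearr) + 1L]] <- data.frame(
        type = "inversion", branch = branch, copy = copy,
        detail = paste(genes_in, collapse = ","), stringsAsFactors = FALSE)
    } else if (ev == "tandem_dup") {
      gp <- gene_pos(elements)
      anc_gp <- gp[vapply(elements[gp], function(e)
        !isTRUE(e$foreign) && !is.na(e$anc), TRUE)]
      if (!length(anc_gp)) next
      at <- if (length(anc_gp) == 1L) anc_gp else sample(anc_gp, 1L)
      dup <- elements[[at]]
      dup$id <- paste0(dup$id, "_d", log_env$dup_counter)
      log_env$dup_counter <- log_env$dup_counter + 1L
      # the duplicated segment carries ~3 kb of flanking spacer so the two
      # copies are resolvable as separate loci under the 2-kb locus rule
      spacer <- list(type = "igs", seq = random_dna(3000L))
      elements <- append(elements, list(spacer, dup), after = at)
      log_env$rearr[[length(log_env$rearr) + 1L]] <- data.frame(
        type = "tandem_dup", branch = branch, copy = copy,
        detail = elements[[at]]$id, stringsAsFactors = FALSE)
    } else if (ev == "foreign_insertion") {
      fg_id <- paste0("fg", log_env$fg_counter)
      log_env$fg_counter <- log_env$fg_counter + 1L
      sense <- which(codon_aa() != "*")
      stops <- which(codon_aa() == "*")
      k <- sample(40:120, 1L)
      cod <- sample(sense, k, replace = TRUE)
      cod[1L] <- match("ATG", codon_universe())
      cod[k] <- sample(stops, 1L)
      fg <- list(type = "gene", id = fg_id, anc = NA_character_,
                 strand = sample(c("+", "-"), 1L),
                 exon_codons = list(cod), exon_anc = 1L,
                 introns = character(0), foreign = TRUE)
      at <- sample(seq_along(elements), 1L)
      elements <- append(elements, list(fg), after = at)
      log_env$rearr[[length(log_env$rearr) + 1L]] <- data.frame(
        type = "foreign_insertion", branch = branch, copy = copy,
        detail = fg_id, stringsAsFactors = FALSE)
    } else if (ev == "te_insertion") {
      len <- max(200L, as.integer(round(stats::rnorm(1, params$te_len_bp,
                                                     params$te_len_bp / 4))))
      te <- list(type = "te", seq = random_dna(len))
      at <- sample(seq_along(elements), 1L)
      elements <- append(elements, list(te), after = at)
      log_env$rearr[[length(log_env$rearr) + 1L]] <- data.frame(
        type = "te_insertion", branch = branch, copy = copy,
        detail = paste0(len, "bp"), stringsAsFactors = FALSE)
    }
  }
  elements
}

#' Evolve a triplicated ancestral region along the species tree
#'
#' Triplicates the ancestor into three sub-genome copies (LF, MF1, MF2) at
#' the WGT node and evolves each copy independently along
#' `(((A,C),B), REF)`: codon sites mutate so that the expected synonymous
#' divergence between two tips separated by time T is `2 mu T`; exons are
#' deleted per branch with the sub-genome bias; structural events are
#' applied and logged.  `REF` stays an unevolved copy of the ancestor (the
#' outgroup witness of the ancestral state).
#'
#' @param ancestor a [simulate_ancestral_region()] result.
#' @param params an [evolution_params()].
#' @return list with `copies` (named list of nine evolved `genome_copy`
#'   objects, `A_LF` .. `C_MF2`), `ref` (the ancestor relabelled), and
#'   `truth` (class `truth_record`: `ortholog_map`, `loss_events`,
#'   `rearrangements`, `expected_ks`, `saturation_warning`).
#' @export
evolve_polyploid_genomes <- function(ancestor, params = evolution_params()) {
  stopifnot(inherits(ancestor, "genome_copy"), inherits(params, "evolution_params"))
  set.seed(params$seed)
  lens <- branch_lengths(params)
  log_env <- new.env(parent = emptyenv())
  log_env$losses <- list()
  log_env$rearr <- list()
  log_env$fg_counter <- 1L
  log_env$dup_counter <- 1L
  # pre-draw which copy each structural event hits, branch by branch
  plan <- list()
  for (b in BRANCHES) {
    ev <- c(rep("inversion", params$n_inversions[[b]]),
            rep("tandem_dup", params$n_tandem_dups[[b]]),
            rep("foreign_insertion", params$n_foreign_insertions[[b]]),
            rep("te_insertion", params$n_te_insertions[[b]]))
    plan[[b]] <- if (length(ev)) {
      data.frame(event = ev, copy = sample(SUBGENOMES, length(ev), replace = TRUE),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(event = character(0), copy = character(0))
    }
  }
  ev_for <- function(b, cp) plan[[b]]$event[plan[[b]]$copy == cp]
  copies <- list()
  for (cp in SUBGENOMES) {
    root <- ancestor$elements
    n_abc <- evolve_branch(root, "stem_ABC", cp, lens[["stem_ABC"]], params,
                           ev_for("stem_ABC", cp), log_env)
    tip_b <- evolve_branch(n_abc, "term_B", cp, lens[["term_B"]], params,
                           ev_for("term_B", cp), log_env)
    n_ac <- evolve_branch(n_abc, "stem_AC", cp, lens[["stem_AC"]], params,
                          ev_for("stem_AC", cp), log_env)
    tip_a <- evolve_branch(n_ac, "term_A", cp, lens[["term_A"]], params,
                           ev_for("term_A", cp), log_env)
    tip_c <- evolve_branch(n_ac, "term_C", cp, lens[["term_C"]], params,
                           ev_for("term_C", cp), log_env)
    copies[[paste0("A_", cp)]] <- assemble_copy(tip_a, "A", cp)
    copies[[paste0("B_", cp)]] <- assemble_copy(tip_b, "B", cp)
    copies[[paste0("C_", cp)]] <- assemble_copy(tip_c, "C", cp)
  }
  copies <- copies[as.vector(outer(c("A", "B", "C"), SUBGENOMES, paste, sep = "_"))]
  # truth record
  anc_genes <- ancestor$genes$id
  omap <- lapply(names(copies), function(nm) {
    cpy <- copies[[nm]]
    anc_of <- stats::setNames(cpy$genes$ancestral_id, cpy$genes$id)
    loci <- table(factor(anc_of, levels = anc_genes))
    ex <- table(factor(anc_of[cpy$exons$gene_id], levels = anc_genes))
    data.frame(gene = anc_genes, genome = cpy$genome, copy = cpy$copy,
               present = as.integer(loci) > 0L,
               n_loci = as.integer(loci), n_exons = as.integer(ex),
               stringsAsFactors = FALSE)
  })
  expected_ks <- data.frame(
    split = c("ac_split", "b_split", "wgt"),
    t_mya = c(params$t_ac_split_mya, params$t_b_split_mya, params$t_wgt_mya),
    expected_ks = 2 * params$mu * 1e6 *
      c(params$t_ac_split_mya, params$t_b_split_mya, params$t_wgt_mya)
  )
  truth <- list(
    ortholog_map = do.call(rbind, omap),
    loss_events = if (length(log_env$losses)) do.call(rbind, log_env$losses) else
      data.frame(branch = character(0), copy = character(0),
                 gene = character(0), exon = integer(0)),
    rearrangements = if (length(log_env$rearr)) do.call(rbind, log_env$rearr) else
      data.frame(type = character(0), branch = character(0),
                 copy = character(0), detail = character(0)),
    expected_ks = expected_ks,
    saturation_warning = any(expected_ks$expected_ks > 1)
  )
  class(truth) <- "truth_record"
  ref <- ancestor
  ref$genome <- "REF"
  ref$copy <- "REF"
  list(copies = copies, ref = ref, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("truth_record: %d loss events, %d rearrangements%s\n",
              nrow(x$loss_events), nrow(x$rearrangements),
              if (x$saturation_warning) " [Ks saturation warning]" else ""))
  invisible(x)
}

#' Extract the CDS of an annotated gene copy
#'
#' Concatenates the gene's exon sequences in CDS order, reverse-complementing
#' minus-strand genes, for Ks estimation between ortholog copies.  Because
#' fractionation removes whole exons, two ortholog copies may retain
#' different exon subsets; passing the shared ancestral exon indices via
#' `anc_exons` restricts both extractions to homologous material (exon
#' lengths are codon multiples, so any subset stays in frame).
#'
#' @param copy a `genome_copy`.
#' @param gene_id a gene id present in `copy$genes`.
#' @param anc_exons optional integer vector of ancestral exon indices to
#'   keep (default: all annotated exons of the gene).
#' @return the CDS as a character string.
#' @export
gene_cds <- function(copy, gene_id, anc_exons = NULL) {
  stopifnot(inherits(copy, "genome_copy"))
  gi <- match(gene_id, copy$genes$id)
  if (is.na(gi)) stop("gene not annotated in this copy: ", gene_id)
  ex <- copy$exons[copy$exons$gene_id == gene_id, , drop = FALSE]
  if (!is.null(anc_exons)) ex <- ex[ex$anc_index %in% anc_exons, , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exons selected for gene ", gene_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  seqs <- substring(copy$sequence, ex$start, ex$end)
  cds <- paste(seqs, collapse = "")
  if (copy$genes$strand[gi] == "-") cds <- revcomp(cds)
  cds
}
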