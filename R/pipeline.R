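# End-to-end orchestration: simulate -> screen -> map -> orthologs -> Ks ->
# fractionation -> loss attribution, with per-stage seeds, TSV/JSON reports
# and a manifest.

#' Default pipeline configuration
#'
#' A nested list mirroring a YAML config file: simulation scale, evolution
#' and BAC-library parameters, homology thresholds, assembly parameters and
#' report options.  The demo scale (17 genes per region, a ~2 Mb cloneable
#' genome at 10x coverage) runs end to end in well under ten minutes on one
#' CPU.
#'
#' @param seed global seed; per-stage seeds are derived with [stage_seed()].
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    region = list(n_genes = 17, mean_exons_per_gene = 3,
                  mean_exon_len = 150, mean_intergenic_len = 600,
                  mean_intron_len = 120),
    evolution = list(),          # overrides for evolution_params()
    library = list(coverage = 10, insert_mean_bp = 130000,
                   insert_sd_bp = 13000, empty_clone_prob = 0.018,
                   total_bp = 2e6, spacer_bp = 50000, min_overlap_bp = 500),
    homology = list(min_id = 70, min_cov = 0.5),
    assembly = list(),           # overrides for assembly_params()
    ks = list(mu = 1.5e-8)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

#' Per-gene Ks/Ka estimates between two genome copies
#'
#' Pairs annotated ortholog CDSs by ancestral id (first locus each) and
#' runs [codon_align()] + [estimate_ks_ka()] per gene.  Only exons retained
#' in both copies are compared: fractionation removes whole exons, so the
#' remaining exon sets need not coincide, and aligning disjoint exon sets
#' would compare non-homologous sequence.
#'
#' @param copy_x,copy_y two `genome_copy` objects.
#' @return data frame with one row per comparable ortholog pair: `gene`,
#'   `S`, `N`, `Sd`, `Nd`, `ks`, `ka`, `saturated`.
#' @export
pairwise_ks <- function(copy_x, copy_y) {
  gx <- copy_x$genes[!is.na(copy_x$genes$ancestral_id), , drop = FALSE]
  gy <- copy_y$genes[!is.na(copy_y$genes$ancestral_id), , drop = FALSE]
  shared <- intersect(gx$ancestral_id, gy$ancestral_id)
  out <- lapply(shared, function(anc) {
    idx <- gx$id[match(anc, gx$ancestral_id)]
    idy <- gy$id[match(anc, gy$ancestral_id)]
    common <- intersect(
      copy_x$exons$anc_index[copy_x$exons$gene_id == idx],
      copy_y$exons$anc_index[copy_y$exons$gene_id == idy])
    if (!length(common)) return(NULL)
    est <- tryCatch(
      estimate_ks_ka(codon_align(gene_cds(copy_x, idx, common),
                                 gene_cds(copy_y, idy, common),
                                 ids = c(idx, idy))),
      error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(gene = anc, S = est$S, N = est$N, Sd = est$Sd, Nd = est$Nd,
               ks = est$ks, ka = est$ka, saturated = est$saturated,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(gene = character(0), S = numeric(0), N = numeric(0),
                      Sd = numeric(0), Nd = numeric(0), ks = numeric(0),
                      ka = numeric(0), saturated = logical(0)))
  }
  do.call(rbind, out)
}

#' Run the full comparative pipeline
#'
#' Executes, in order: region simulation and polyploid evolution (with
#' truth logging); BAC library construction, probe screen and library
#' statistics; fingerprint contig assembly and its truth evaluation;
#' ortholog detection and the presence matrix; per-pair Ks estimation and
#' divergence dating; per-region fractionation statistics with sub-genome
#' ranking; and Dollo branch-loss attribution.  All outputs are written to
#' `outdir` (FASTA, GFF3, TSV reports, JSON manifest) and also returned.
#' The same config and seed give a byte-identical report set.
#'
#' @param config configuration list ([default_config()] / [read_config()]).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with all stage results.
#' @export
run_end_to_end <- function(config = default_config(), outdir = tempfile("hexafrac_")) {
  if (!is.list(config)) stop("config must be a list")
  if (!isTRUE(config$region$n_genes >= 1)) {
    stop("config error: region$n_genes must be >= 1")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list(config = config, outdir = outdir)

  # -- simulate ------------------------------------------------------------
  res$ancestor <- stage("simulate", {
    rg <- config$region
    simulate_ancestral_region(rg$n_genes, rg$mean_exons_per_gene,
                              rg$mean_exon_len, rg$mean_intergenic_len,
                              rg$mean_intron_len,
                              seed = stage_seed(config$seed, "simulate"))
  })
  res$evolved <- stage("simulate", {
    ep <- do.call(evolution_params,
                  c(config$evolution,
                    list(seed = stage_seed(config$seed, "evolve"))))
    evolve_polyploid_genomes(res$ancestor, ep)
  })
  stage("simulate", {
    seqs <- c(REF = res$ancestor$sequence,
              vapply(res$evolved$copies, `[[`, "", "sequence"))
    write_fasta(seqs, file.path(outdir, "genomes.fasta"))
    feats <- do.call(rbind, c(list(copy_to_features(res$evolved$ref)),
                              lapply(res$evolved$copies, copy_to_features)))
    feats$ID <- paste(feats$seqid, feats$ID, sep = ":")
    feats$Parent <- ifelse(is.na(feats$Parent), NA,
                           paste(feats$seqid, feats$Parent, sep = ":"))
    write_gff3(feats, file.path(outdir, "genomes.gff3"))
    tr <- res$evolved$truth
    utils::write.table(tr$loss_events, file.path(outdir, "truth_losses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tr$rearrangements,
                       file.path(outdir, "truth_rearrangements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tr$ortholog_map, file.path(outdir, "truth_orthologs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- BAC library + probe screen -----------------------------------------
  res$bac <- stage("bac_library", {
    lc <- config$library
    b_copies <- res$evolved$copies[grep("^B_", names(res$evolved$copies))]
    cg <- concat_genome(b_copies, spacer_bp = lc$spacer_bp,
                        total_bp = lc$total_bp,
                        seed = stage_seed(config$seed, "concat"))
    n_clones <- max(10L, as.integer(round(
      lc$coverage * nchar(cg$sequence) / lc$insert_mean_bp)))
    lib <- simulate_bac_library(cg$sequence, bac_library_params(
      n_clones = n_clones, insert_mean_bp = lc$insert_mean_bp,
      insert_sd_bp = lc$insert_sd_bp, empty_clone_prob = lc$empty_clone_prob,
      seed = stage_seed(config$seed, "library")))
    screen <- simulate_probe_screen(lib$clones, cg$loci,
                                    min_overlap_bp = lc$min_overlap_bp)
    list(genome = cg, library = lib, screen = screen)
  })
  stage("bac_library", {
    write_report(report_table("probe_screen", res$bac$screen$table,
                              rounding = list(mean_redundancy =
                                                list(digits = 1, mode = "down"))),
                 file.path(outdir, "probe_screen.tsv"))
  })

  # -- fingerprint map -----------------------------------------------------
  res$fpmap <- stage("fingerprint_map", {
    ap <- do.call(assembly_params, config$assembly)
    keep <- !res$bac$library$clones$empty
    contigs <- assemble_stepwise(res$bac$library$fingerprints[keep], ap)
    eval <- evaluate_assembly(contigs, res$bac$library$clones[keep, ])
    list(contigs = contigs, eval = eval)
  })
  stage("fingerprint_map", {
    ct <- res$fpmap$contigs
    df <- data.frame(contig = rep(names(ct$contigs), lengths(ct$contigs)),
                     clone = unlist(ct$contigs), stringsAsFactors = FALSE)
    utils::write.table(df, file.path(outdir, "fp_contigs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  # -- orthologs / presence matrix ----------------------------------------
  res$presence <- stage("orthologs", {
    build_presence_matrix(res$evolved$ref, res$evolved$copies,
                          min_id = config$homology$min_id,
                          min_cov = config$homology$min_cov)
  })
  stage("orthologs", {
    pm <- res$presence
    df <- data.frame(gene = pm$rows$gene, exon = pm$rows$exon,
                     pm$retained, check.names = FALSE)
    utils::write.table(df, file.path(outdir, "presence_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- Ks / divergence dating ---------------------------------------------
  res$divergence <- stage("ks", {
    cps <- res$evolved$copies
    pairs <- list(
      A_vs_C = list(cps$A_LF, cps$C_LF),
      B_vs_A = list(cps$B_LF, cps$A_LF),
      B_vs_C = list(cps$B_LF, cps$C_LF),
      WGT_LF_MF1 = list(cps$B_LF, cps$B_MF1)
    )
    summaries <- lapply(names(pairs), function(nm) {
      tab <- pairwise_ks(pairs[[nm]][[1L]], pairs[[nm]][[2L]])
      tab <- tab[!tab$saturated & !is.na(tab$ks), , drop = FALSE]
      if (!nrow(tab)) return(NULL)
      s <- summarize_pairwise(tab$ks, pair = nm, mu = config$ks$mu)
      data.frame(pair = nm, n_genes = s$n_genes, mean_ks = s$mean_ks,
                 sd_ks = s$sd_ks, mean_mya = s$mean_mya, sd_mya = s$sd_mya,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, summaries[!vapply(summaries, is.null, TRUE)])
  })
  stage("ks", {
    write_report(report_table("divergence", res$divergence,
                              rounding = list(mean_ks = 2, sd_ks = 2,
                                              mean_mya = 2, sd_mya = 2)),
                 file.path(outdir, "divergence.tsv"))
  })

  # -- fractionation stats + ranking --------------------------------------
  res$region_stats <- stage("stats", {
    lapply(res$evolved$copies, function(cp) region_stats(res$presence, cp))
  })
  res$ranking <- stage("stats", {
    lapply(stats::setNames(c("A", "B", "C"), c("A", "B", "C")), function(g) {
      rank_subgenomes(res$region_stats[grep(paste0("^", g, "_"),
                                            names(res$region_stats))])
    })
  })
  stage("stats", {
    rs <- do.call(rbind, lapply(res$region_stats, function(s)
      data.frame(region = s$region, size_bp = s$size_bp,
                 n_potential_TEs = s$n_potential_TEs,
                 retained_exons = s$retained_exons,
                 retained_exons_pct = s$retained_exons_pct,
                 retained_genic = s$retained_genic,
                 retained_genic_pct = s$retained_genic_pct,
                 predicted_genes = s$predicted_genes,
                 predicted_genes_pct = s$predicted_genes_pct,
                 n_ab_initio_genes = s$n_ab_initio_genes,
                 gene_density_bp_per_gene = s$gene_density_bp_per_gene,
                 stringsAsFactors = FALSE)))
    write_report(report_table("fractionation", rs,
                              rounding = list(retained_exons_pct = 2,
                                              retained_genic_pct = 2,
                                              predicted_genes_pct = 2,
                                              gene_density_bp_per_gene = 2)),
                 file.path(outdir, "fractionation.tsv"))
  })

  # -- loss attribution ----------------------------------------------------
  res$branch_losses <- stage("attribute_loss", {
    branch_fractionation(res$presence)
  })
  stage("attribute_loss", {
    bl <- res$branch_losses
    df <- data.frame(branch = rownames(bl$counts), bl$counts,
                     check.names = FALSE)
    utils::write.table(df, file.path(outdir, "branch_losses.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  # -- manifest ------------------------------------------------------------
  manifest <- list(
    package = "hexafrac",
    version = as.character(utils::packageVersion("hexafrac")),
    seed = config$seed,
    config = config,
    config_hash = config_hash(config),
    outputs = list.files(outdir)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

# Internal: stable hash of a configuration (serialisation checksum).
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2L)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251L + 1L)) %%
            .Machine$integer.max)
}

#' Render stage outputs as TSV and JSON report files
#'
#' Writes each named data frame under the io rounding rules in both
#' formats; a missing (`NULL`) stage yields an explicit `"stage not run"`
#' placeholder file instead of an error.
#'
#' @param outputs named list of data frames (or `NULL` placeholders).
#' @param outdir output directory.
#' @param rounding named list of per-table rounding specs.
#' @return character vector of files written, invisibly.
#' @export
render_reports <- function(outputs, outdir, rounding = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(outputs)) {
    base <- file.path(outdir, nm)
    if (is.null(outputs[[nm]])) {
      writeLines(paste0("stage not run: ", nm), paste0(base, ".tsv"))
      written <- c(written, paste0(base, ".tsv"))
      next
    }
    tb <- report_table(nm, outputs[[nm]],
                       rounding = if (nm %in% names(rounding)) rounding[[nm]] else list())
    write_report(tb, paste0(base, ".tsv"), "tsv")
    write_report(tb, paste0(base, ".json"), "json")
    written <- c(written, paste0(base, c(".tsv", ".json")))
  }
  invisible(written)
}
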