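# FASTA / GFF3 / report-table I/O.  Parsing and serialisation of the
# standard formats is delegated to Biostrings and rtracklayer; this layer
# adds the validation and rounding contracts the pipeline relies on.

#' Read a FASTA file
#'
#' Reads DNA records, uppercasing any lowercase bases (with a message).
#' Duplicate ids, empty sequences or non-IUPAC characters raise a format
#' error naming the offending record; an empty file returns an empty vector
#' with a warning.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    warning("FASTA file is empty: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(recs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  seqs <- as.character(recs)
  if (any(grepl("[a-z]", seqs))) {
    message("read_fasta: lowercase bases uppercased in ", path)
    seqs <- toupper(seqs)
  }
  empty <- nchar(seqs) == 0L
  if (any(empty)) stop("empty sequence for record '", ids[which(empty)[1L]], "'")
  iupac <- "^[ACGTRYSWKMBDHVN-]+$"
  bad <- !grepl(iupac, seqs)
  if (any(bad)) stop("non-IUPAC characters in record '", ids[which(bad)[1L]], "'")
  stats::setNames(seqs, ids)
}

#' Write a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param wrap line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  stopifnot(is.character(records), wrap >= 1)
  if (length(records) > 0 && is.null(names(records))) {
    stop("records must be named")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(records), path, width = wrap)
  invisible(path)
}

# Internal: quick structural scan of a GFF3 file, reporting 1-based line
# numbers for malformed rows before handing off to rtracklayer.
validate_gff3_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) stop("GFF3 line ", i, ": expected 9 columns, got ", length(f))
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e)) stop("GFF3 line ", i, ": non-numeric coordinates")
    if (s < 1L) stop("GFF3 line ", i, ": start < 1")
    if (e < s) stop("GFF3 line ", i, ": end < start")
    if (!f[7L] %in% c("+", "-", ".")) stop("GFF3 line ", i, ": unknown strand '", f[7L], "'")
  }
  invisible(TRUE)
}

#' Read a GFF3 annotation
#'
#' Validates the raw file (column count, coordinates, strand — errors carry
#' the line number), parses it with rtracklayer, and checks that every
#' `Parent` attribute refers to an `ID` defined in the file.
#'
#' @param path path to a GFF3 file.
#' @return data frame with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `strand`, `ID`, `Parent`, `ancestral_id` (coordinates 1-based
#'   inclusive; missing attributes are `NA`).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(nm) {
    if (!nm %in% names(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[nm]]
    if (methods::is(v, "CharacterList")) {
      v <- vapply(v, function(x) if (length(x)) x[[1L]] else NA_character_, "")
    }
    as.character(v)
  }
  feats <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    source = get_attr("source"),
    type = as.character(mc$type),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    ID = get_attr("ID"),
    Parent = get_attr("Parent"),
    ancestral_id = get_attr("ancestral_id"),
    stringsAsFactors = FALSE
  )
  feats$strand[feats$strand == "*"] <- "."
  orphan <- !is.na(feats$Parent) & !(feats$Parent %in% feats$ID)
  if (any(orphan)) {
    stop("GFF3 Parent '", feats$Parent[which(orphan)[1L]],
         "' has no matching ID in ", path)
  }
  feats
}

#' Write a GFF3 annotation
#'
#' Inverse of [read_gff3()]: a read of the written file reproduces the
#' feature set exactly (coordinates are stored 1-based inclusive
#' throughout, so no conversion is involved).
#'
#' @param features data frame as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  need <- c("seqid", "type", "start", "end", "strand", "ID")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("features lack columns: ", paste(miss, collapse = ", "))
  stopifnot(all(features$end >= features$start), all(features$start >= 1))
  if (anyDuplicated(features$ID[!is.na(features$ID)])) {
    stop("feature IDs must be unique per file")
  }
  strand <- features$strand
  strand[is.na(strand) | strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = strand
  )
  mc <- S4Vectors::DataFrame(
    source = if ("source" %in% names(features)) features$source else "hexafrac",
    type = features$type,
    ID = features$ID
  )
  if ("Parent" %in% names(features)) mc$Parent <- features$Parent
  if ("ancestral_id" %in% names(features)) mc$ancestral_id <- features$ancestral_id
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Convert a genome copy's annotation to GFF3 features
#'
#' Genes become `gene` features (with `ancestral_id`), exons become `exon`
#' children, TE-like insertions become `TE` features.
#'
#' @param copy a `genome_copy`.
#' @return a feature data frame accepted by [write_gff3()].
#' @export
copy_to_features <- function(copy) {
  stopifnot(inherits(copy, "genome_copy"))
  seqid <- paste(copy$genome, copy$copy, sep = "_")
  rows <- list()
  g <- copy$genes
  if (nrow(g)) {
    rows[[1L]] <- data.frame(
      seqid = seqid, source = "hexafrac", type = "gene",
      start = g$start, end = g$end, strand = g$strand,
      ID = g$id, Parent = NA_character_, ancestral_id = g$ancestral_id,
      stringsAsFactors = FALSE)
    ex <- copy$exons
    rows[[2L]] <- data.frame(
      seqid = seqid, source = "hexafrac", type = "exon",
      start = ex$start, end = ex$end,
      strand = g$strand[match(ex$gene_id, g$id)],
      ID = paste0(ex$gene_id, ".e", ex$anc_index),
      Parent = ex$gene_id, ancestral_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (nrow(copy$tes)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = seqid, source = "hexafrac", type = "TE",
      start = copy$tes$start, end = copy$tes$end, strand = ".",
      ID = paste0(seqid, ".te", seq_len(nrow(copy$tes))),
      Parent = NA_character_, ancestral_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      ID = character(0), Parent = character(0),
                      ancestral_id = character(0)))
  }
  do.call(rbind, rows)
}

#' Build a report table with a per-column rounding specification
#'
#' @param name table name.
#' @param data data frame of cells.
#' @param rounding named list: column name -> list(digits, mode) with mode
#'   `"up"` (half away from zero, the default) or `"down"` (half toward
#'   zero).  A bare integer is shorthand for `list(digits = n, mode = "up")`.
#' @return list of class `report_table`.
#' @export
report_table <- function(name, data, rounding = list()) {
  stopifnot(is.character(name), is.data.frame(data), is.list(rounding))
  bad <- setdiff(names(rounding), names(data))
  if (length(bad)) stop("rounding spec for unknown column(s): ",
                        paste(bad, collapse = ", "))
  rounding <- lapply(rounding, function(r) {
    if (is.numeric(r)) r <- list(digits = r, mode = "up")
    stopifnot(r$mode %in% c("up", "down"))
    r
  })
  structure(list(name = name, data = data, rounding = rounding),
            class = "report_table")
}

# Internal: apply a report table's rounding spec, returning a data frame of
# rounded numerics (other columns untouched).
rounded_data <- function(table) {
  d <- table$data
  for (col in names(table$rounding)) {
    r <- table$rounding[[col]]
    d[[col]] <- if (r$mode == "up") round_half_up(d[[col]], r$digits) else
      round_half_down(d[[col]], r$digits)
  }
  d
}

#' Write a report table as TSV or JSON
#'
#' Numeric cells are rendered under the table's rounding spec; TSV cells
#' keep trailing zeros (`53.35`, `8.7`) and the JSON rendering contains the
#' identical numbers.  An empty table yields a header-only file.
#'
#' @param table a [report_table()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, format = c("tsv", "json")) {
  stopifnot(inherits(table, "report_table"))
  format <- match.arg(format)
  d <- rounded_data(table)
  if (format == "tsv") {
    out <- d
    for (col in names(table$rounding)) {
      r <- table$rounding[[col]]
      out[[col]] <- ifelse(is.na(d[[col]]), "NA",
                           formatC(d[[col]], format = "f", digits = r$digits))
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(name = table$name, rows = d), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
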