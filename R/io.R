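#' Read a genome QC table
#'
#' Tab-separated table with columns `genome_id`, `taxonomy`, `completeness`,
#' `contamination`. An optional two-column category map
#' (`genome_id`, `category`) attaches metabolic-category labels
#' (methanogen / ANME-1 / ANME-2 / ANKA / unknown); unmapped genomes get
#' `"unknown"`.
#'
#' @param path Path to the genome TSV.
#' @param category_map Optional path to the category-map TSV.
#' @return Data frame of genome records.
#' @export
read_genome_table <- function(path, category_map = NULL) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "completeness", "contamination")
  if (!all(need %in% names(g))) {
    stop("genome table must have columns: ", paste(need, collapse = ", "))
  }
  g$category <- "unknown"
  if (!is.null(category_map)) {
    m <- utils::read.delim(category_map, stringsAsFactors = FALSE)
    stopifnot(all(c("genome_id", "category") %in% names(m)))
    idx <- match(g$genome_id, m$genome_id)
    g$category[!is.na(idx)] <- m$category[idx[!is.na(idx)]]
  }
  g
}

#' Read gene features from GFF3 or TSV
#'
#' GFF3 files (extension `.gff`/`.gff3`) are parsed with rtracklayer;
#' `gene`/`CDS` records are kept, `gene_id` is taken from the `ID`
#' attribute and `genome_id` from a `genome_id` attribute (falling back to
#' the contig name if absent). Any other extension is read as a 6-column
#' TSV (`genome_id`, `contig_id`, `gene_id`, `start`, `end`, `strand`).
#' Coordinates are 1-based inclusive throughout.
#'
#' @param path Path to the feature file.
#' @return Data frame of gene features.
#' @export
read_features <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- S4Vectors::mcols(gr)
    keep <- if ("type" %in% names(meta)) {
      as.character(meta$type) %in% c("gene", "CDS")
    } else rep(TRUE, length(gr))
    gr <- gr[keep]
    meta <- S4Vectors::mcols(gr)
    contig <- as.character(GenomicRanges::seqnames(gr))
    out <- data.frame(
      genome_id = if ("genome_id" %in% names(meta)) {
        as.character(meta$genome_id)
      } else contig,
      contig_id = contig,
      gene_id = as.character(meta$ID),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand")
  if (!all(need %in% names(out))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(out$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'")
  }
  if (any(out$start < 1L | out$start > out$end)) {
    stop("features must satisfy 1 <= start <= end")
  }
  out[, need]
}

#' Read homology hits in BLAST tabular (outfmt 6) form
#'
#' Standard 12-column tabular output without header. The query name is
#' expected to follow the convention `<source>|mcr<X>` (e.g.
#' `M_maripaludis|mcrA`), from which the reference organism and the query
#' subunit letter are parsed.
#'
#' @param path Path to the tabular hit file.
#' @return Data frame with columns `query_source`, `query_subunit`,
#'   `subject_gene_id`, `identity_pct`, `evalue`, `bitscore`.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  h <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(h) != 12L) stop("expected 12-column BLAST tabular output")
  names(h) <- cols
  m <- regmatches(h$qseqid, regexec("^(.*)\\|mcr([ABCDG])$", h$qseqid))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("query name(s) not of the form '<source>|mcr<X>': ",
         paste(utils::head(unique(h$qseqid[bad]), 3), collapse = ", "))
  }
  data.frame(
    query_source = vapply(m, `[`, character(1), 2L),
    query_subunit = vapply(m, `[`, character(1), 3L),
    subject_gene_id = h$sseqid,
    identity_pct = h$pident,
    evalue = h$evalue,
    bitscore = h$bitscore,
    stringsAsFactors = FALSE
  )
}

#' Write mining outputs
#'
#' Writes `operons.tsv` (one operon call per row), `genome_summary.tsv`,
#' and `tree_rings.tsv`, a circular-tree annotation ring file
#' (`genome_id`, `ring_index`, `label`, `color`) in which each mcr copy of
#' a genome occupies one ring, colored by architecture.
#'
#' @param mining Result of [mine_operons()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_mining_outputs <- function(mining, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    operons = file.path(dir, "operons.tsv"),
    summary = file.path(dir, "genome_summary.tsv"),
    rings = file.path(dir, "tree_rings.tsv")
  )
  utils::write.table(mining$operons, paths[["operons"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mining$summary, paths[["summary"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ring_color <- c(mcrBDCGA = "blue", mcrBDGA = "cyan", mcrBGA = "magenta",
                  mcrBAG = "orange", unusual = "black")
  ops <- mining$operons
  rings <- data.frame(
    genome_id = ops$genome_id,
    ring_index = stats::ave(seq_len(nrow(ops)), ops$genome_id,
                            FUN = seq_along),
    label = ops$label,
    color = unname(ring_color[ops$label]),
    stringsAsFactors = FALSE
  )
  utils::write.table(rings, paths[["rings"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read an intact-MS peak list
#'
#' CSV with column `mz` (Thomson) and optionally `z` (positive integer
#' charge).
#'
#' @param path Path to the CSV.
#' @return Data frame with columns `mz` and (if present) `z`.
#' @export
read_peak_list <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(p)) stop("peak list must have an 'mz' column")
  if (any(p$mz <= 0)) stop("m/z values must be positive")
  if ("z" %in% names(p) && any(!is.na(p$z) & p$z < 1)) {
    stop("charges must be >= 1")
  }
  p
}

#' Read a peptide quantification table
#'
#' CSV with columns `construct`, `subunit`, `peptide`, `area` and optional
#' `position`, `delta_da` for modification bookkeeping.
#'
#' @param path Path to the CSV.
#' @return Data frame of peptide observations.
#' @export
read_peptide_table <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct", "subunit", "peptide", "area")
  if (!all(need %in% names(p))) {
    stop("peptide table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(p$area < 0)) stop("peak areas must be nonnegative")
  p
}
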