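#' Mining configuration
#'
#' Bundles the thresholds used throughout operon mining: genome quality
#' cutoffs, the homology E-value cutoff, and the intergenic-distance rule
#' used to chain mcr genes into operons.
#'
#' @param min_completeness Minimum genome completeness in percent. The bound
#'   is exclusive: a genome is kept only if completeness is strictly greater.
#' @param max_contamination Maximum genome contamination in percent,
#'   exclusive (kept only if strictly smaller).
#' @param max_evalue Largest E-value retained for homology hits. Inclusive:
#'   a hit at exactly this value is kept; only strictly larger values are
#'   discarded.
#' @param max_gap_bp Intergenic-distance threshold in bp. Two adjacent mcr
#'   genes on the same contig and strand are chained into one operon iff
#'   the gap between them is strictly smaller than this value.
#'
#' @return A list of class `mining_config`.
#' @export
#' @examples
#' cfg <- mining_config()
#' cfg$max_gap_bp
mining_config <- function(min_completeness = 80,
                          max_contamination = 10,
                          max_evalue = 1e-5,
                          max_gap_bp = 250) {
  stopifnot(min_completeness > 0, max_contamination > 0,
            max_evalue > 0, max_gap_bp > 0)
  structure(
    list(min_completeness = min_completeness,
         max_contamination = max_contamination,
         max_evalue = max_evalue,
         max_gap_bp = max_gap_bp),
    class = "mining_config"
  )
}

#' Filter genomes on completeness and contamination
#'
#' Keeps genomes with completeness strictly above `min_completeness` and
#' contamination strictly below `max_contamination` (CheckM-style
#' estimates). Records with a missing estimate are dropped with a warning
#' rather than an error, so one bad row does not abort a genome-scale scan.
#'
#' @param genomes Data frame with columns `genome_id`, `completeness`,
#'   `contamination` (and optionally `taxonomy`, `category`).
#' @param config A [mining_config()].
#'
#' @return The qualifying subset of `genomes`, input order preserved.
#' @export
qc_filter <- function(genomes, config = mining_config()) {
  stopifnot(is.data.frame(genomes),
            all(c("genome_id", "completeness", "contamination") %in%
                  names(genomes)))
  bad <- !is.finite(genomes$completeness) | !is.finite(genomes$contamination)
  if (any(bad)) {
    warning(sum(bad), " genome record(s) rejected: missing completeness or ",
            "contamination estimate")
  }
  keep <- !bad &
    genomes$completeness > config$min_completeness &
    genomes$contamination < config$max_contamination
  genomes[keep, , drop = FALSE]
}

#' Filter homology hits by E-value
#'
#' Discards hits whose E-value is strictly larger than `max_evalue`; a hit
#' at exactly the cutoff is retained.
#'
#' @param hits Data frame with at least an `evalue` column (see
#'   [read_blast_hits()]).
#' @param config A [mining_config()].
#'
#' @return The retained subset of `hits`, input order preserved.
#' @export
filter_hits <- function(hits, config = mining_config()) {
  stopifnot(is.data.frame(hits), "evalue" %in% names(hits))
  if (any(!is.finite(hits$evalue)) || any(hits$evalue < 0)) {
    stop("hits contain missing or negative E-values")
  }
  hits[hits$evalue <= config$max_evalue, , drop = FALSE]
}

#' Resolve multi-query hits to one subunit per gene
#'
#' A gene may be hit by several query subunits from several reference
#' organisms. Each subject gene receives the subunit of its highest-bitscore
#' hit; ties are broken by lowest E-value, then alphabetically by subunit
#' letter, so the assignment is deterministic.
#'
#' @param hits E-value-filtered hits with columns `subject_gene_id`,
#'   `query_subunit`, `bitscore`, `evalue`.
#'
#' @return Data frame with one row per assigned gene: `gene_id`, `subunit`,
#'   `best_bitscore`, `best_evalue`.
#' @export
assign_subunits <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("subject_gene_id", "query_subunit", "bitscore", "evalue")
                %in% names(hits)))
  if (nrow(hits) == 0L) {
    return(data.frame(gene_id = character(), subunit = character(),
                      best_bitscore = numeric(), best_evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!all(hits$query_subunit %in% MCR_SUBUNITS)) {
    stop("query_subunit outside the {A,B,C,D,G} alphabet")
  }
  ord <- order(hits$subject_gene_id, -hits$bitscore, hits$evalue,
               hits$query_subunit)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$subject_gene_id)
  out <- data.frame(
    gene_id = h$subject_gene_id[first],
    subunit = h$query_subunit[first],
    best_bitscore = h$bitscore[first],
    best_evalue = h$evalue[first],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Chain mcr genes into operon calls
#'
#' Within each (genome, contig, strand), subunit-assigned genes sorted by
#' start coordinate are chained: an adjacent pair is merged into the same
#' operon iff the intergenic gap (`start_next - end_prev - 1`, coordinates
#' 1-based inclusive) is strictly smaller than `config$max_gap_bp`.
#' Non-mcr genes are invisible to the chaining. Member order is coordinate
#' order on the + strand and reversed on the - strand, so the reported
#' pattern always reads 5' to 3' on the coding strand. Overlapping genes
#' (negative gap) are merged with the gap treated as 0, with a warning.
#'
#' @param assignments Output of [assign_subunits()].
#' @param features Gene coordinate table with columns `genome_id`,
#'   `contig_id`, `gene_id`, `start`, `end`, `strand`.
#' @param config A [mining_config()].
#'
#' @return Data frame of operon calls: `genome_id`, `contig_id`, `strand`,
#'   `start`, `end`, `n_genes`, `member_gene_ids` (comma-joined, 5'->3'),
#'   `pattern`, `label`.
#' @export
call_operons <- function(assignments, features, config = mining_config()) {
  stopifnot(is.data.frame(assignments), is.data.frame(features),
            all(c("genome_id", "contig_id", "gene_id", "start", "end",
                  "strand") %in% names(features)))
  empty <- data.frame(
    genome_id = character(), contig_id = character(), strand = character(),
    start = integer(), end = integer(), n_genes = integer(),
    member_gene_ids = character(), pattern = character(),
    label = character(), stringsAsFactors = FALSE
  )
  if (nrow(assignments) == 0L) return(empty)
  missing_feat <- setdiff(assignments$gene_id, features$gene_id)
  if (length(missing_feat) > 0L) {
    stop("assigned gene(s) without a coordinate feature: ",
         paste(utils::head(missing_feat, 5), collapse = ", "))
  }
  df <- merge(assignments, features, by = "gene_id")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$start > df$end)) stop("feature with start > end")

  overlap_warned <- FALSE
  calls <- list()
  for (grp in split(df, list(df$genome_id, df$contig_id, df$strand),
                    drop = TRUE)) {
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    n <- nrow(grp)
    gaps <- if (n > 1L) grp$start[-1L] - grp$end[-n] - 1L else integer()
    if (any(gaps < 0L)) {
      if (!overlap_warned) {
        warning("overlapping mcr genes encountered; gap treated as 0")
        overlap_warned <- TRUE
      }
      gaps <- pmax(gaps, 0L)
    }
    chain <- cumsum(c(0L, as.integer(gaps >= config$max_gap_bp)))
    for (members in split(grp, chain)) {
      if (members$strand[1L] == "-") {
        members <- members[rev(seq_len(nrow(members))), , drop = FALSE]
      }
      calls[[length(calls) + 1L]] <- data.frame(
        genome_id = members$genome_id[1L],
        contig_id = members$contig_id[1L],
        strand = members$strand[1L],
        start = min(members$start),
        end = max(members$end),
        n_genes = nrow(members),
        member_gene_ids = paste(members$gene_id, collapse = ","),
        pattern = paste(members$subunit, collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$genome_id, out$contig_id, out$start), , drop = FALSE]
  out$label <- classify_operon(out$pattern)
  rownames(out) <- NULL
  out
}

#' Classify operon architectures
#'
#' Maps a subunit-letter pattern to its canonical operon label by exact
#' match: `BDCGA -> mcrBDCGA`, `BDGA -> mcrBDGA`, `BGA -> mcrBGA`,
#' `BAG -> mcrBAG`; any other pattern (including repeats such as
#' `BGABGA` and singletons) is `unusual`.
#'
#' @param pattern Character vector of subunit-letter patterns.
#'
#' @return Character vector of labels, same length as `pattern`.
#' @export
#' @examples
#' classify_operon(c("BDCGA", "BAG", "GBA", "A"))
classify_operon <- function(pattern) {
  stopifnot(is.character(pattern), all(nzchar(pattern)))
  if (!all(grepl("^[ABCDG]+$", pattern))) {
    stop("pattern letters must be within {A,B,C,D,G}")
  }
  label <- unname(CANONICAL_OPERONS[pattern])
  label[is.na(label)] <- "unusual"
  label
}

#' Per-genome mcr content summary
#'
#' For each genome, reports whether it encodes a complete catalytic subunit
#' set (at least one gene each assigned to McrA, McrB, and McrG, anywhere in
#' the genome, operon membership not required), its operon-label multiset,
#' and its mcr copy count (number of operon calls containing at least one of
#' the A/B/G subunits).
#'
#' @param calls Output of [call_operons()].
#' @param assignments Output of [assign_subunits()].
#' @param features Gene coordinate table (links gene ids to genomes).
#' @param genomes Genome table; its `category` column (if present) is
#'   carried through.
#'
#' @return Data frame with one row per genome in `genomes`:
#'   `genome_id`, `has_complete_set`, `mcr_copy_count`, `operon_labels`
#'   (comma-joined, sorted), `category`.
#' @export
summarize_genomes <- function(calls, assignments, features, genomes) {
  stopifnot(is.data.frame(genomes), "genome_id" %in% names(genomes))
  unknown <- setdiff(calls$genome_id, genomes$genome_id)
  if (length(unknown) > 0L) {
    stop("operon call(s) for unknown genome_id: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  asg <- merge(assignments, features[, c("gene_id", "genome_id")],
               by = "gene_id")
  has_core <- vapply(genomes$genome_id, function(g) {
    all(c("A", "B", "G") %in% asg$subunit[asg$genome_id == g])
  }, logical(1))
  core_call <- grepl("[ABG]", calls$pattern)
  copy_count <- vapply(genomes$genome_id, function(g) {
    sum(core_call & calls$genome_id == g)
  }, integer(1))
  labels <- vapply(genomes$genome_id, function(g) {
    paste(sort(calls$label[calls$genome_id == g]), collapse = ",")
  }, character(1))
  data.frame(
    genome_id = genomes$genome_id,
    has_complete_set = unname(has_core),
    mcr_copy_count = unname(copy_count),
    operon_labels = unname(labels),
    category = if ("category" %in% names(genomes)) genomes$category
               else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Run the full mining stage on loaded tables
#'
#' Convenience wrapper: QC-filters genomes, E-value-filters hits restricted
#' to QC-passing genomes, assigns subunits, calls and classifies operons,
#' and summarizes per-genome content.
#'
#' @inheritParams qc_filter
#' @inheritParams call_operons
#' @param hits Homology-hit table (see [read_blast_hits()]).
#'
#' @return List with elements `genomes` (QC-passing), `assignments`,
#'   `operons`, `summary`.
#' @export
mine_operons <- function(genomes, features, hits, config = mining_config()) {
  kept <- qc_filter(genomes, config)
  feats <- features[features$genome_id %in% kept$genome_id, , drop = FALSE]
  hits_kept <- filter_hits(hits, config)
  hits_kept <- hits_kept[hits_kept$subject_gene_id %in% feats$gene_id, ,
                         drop = FALSE]
  asg <- assign_subunits(hits_kept)
  ops <- call_operons(asg, feats, config)
  list(
    genomes = kept,
    assignments = asg,
    operons = ops,
    summary = summarize_genomes(ops, asg, feats, kept)
  )
}
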