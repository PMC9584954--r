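#' Classify peptides by proteome of origin
#'
#' Attributes each identified peptide to the host proteome, the
#' recombinant proteome, both, or neither, by exact substring membership
#' in the ortholog sequences. Peptides arrive pre-digested from an
#' upstream identification engine, so no digestion rules are applied here.
#'
#' @param peptides Data frame with a `peptide` column (see
#'   [read_peptide_table()]).
#' @param host_proteome,recombinant_proteome `Biostrings::AAStringSet`
#'   objects, or paths to FASTA files, holding the orthologous subunit
#'   sequences.
#' @return `peptides` with an added `origin` column, one of
#'   `host_unique`, `recombinant_unique`, `shared`, `unmapped`.
#' @export
classify_peptides <- function(peptides, host_proteome,
                              recombinant_proteome) {
  stopifnot(is.data.frame(peptides), "peptide" %in% names(peptides))
  host <- .as_sequences(host_proteome)
  recomb <- .as_sequences(recombinant_proteome)
  in_host <- .in_any(peptides$peptide, host)
  in_recomb <- .in_any(peptides$peptide, recomb)
  origin <- rep("unmapped", nrow(peptides))
  origin[in_host & !in_recomb] <- "host_unique"
  origin[!in_host & in_recomb] <- "recombinant_unique"
  origin[in_host & in_recomb] <- "shared"
  if (any(origin == "unmapped")) {
    message(sum(origin == "unmapped"),
            " peptide(s) matched neither proteome (unmapped)")
  }
  peptides$origin <- origin
  peptides
}

.as_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readAAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  stopifnot(is.character(x), length(x) >= 1L)
  x
}

.in_any <- function(peptides, sequences) {
  vapply(peptides, function(p) {
    any(vapply(sequences, function(s) grepl(p, s, fixed = TRUE),
               logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Host fraction from combined peptide peak areas
#'
#' For each construct, sums the chromatographic peak areas of
#' origin-unique peptides of the requested subunit and reports the host
#' fraction
#' `100 * sum(area host_unique) / (sum(area host_unique) + sum(area
#' recombinant_unique))`. Shared (ortholog-identical) and unmapped
#' peptides are excluded to avoid double counting. Across constructs, the
#' mean and sample standard deviation of the per-construct fractions are
#' reported, the form in which subunit chimerism is usually quoted
#' (e.g. "30 +/- 6% of the total McrG").
#'
#' @param peptides Origin-classified peptide table (see
#'   [classify_peptides()]) with columns `construct`, `subunit`,
#'   `peptide`, `area`, `origin`.
#' @param subunit Subunit letter to quantify (default: all rows).
#' @return List of class `abundance_result`: `subunit`, `per_construct`
#'   (data frame with `construct`, `host_pct`, `recombinant_pct`),
#'   `mean_pct`, `sd_pct`.
#' @export
relative_abundance <- function(peptides, subunit = NULL) {
  stopifnot(is.data.frame(peptides),
            all(c("construct", "area", "origin") %in% names(peptides)))
  if (!is.null(subunit)) {
    peptides <- peptides[peptides$subunit == subunit, , drop = FALSE]
  }
  if (any(peptides$area < 0)) stop("peak areas must be nonnegative")
  per <- lapply(split(peptides, peptides$construct), function(p) {
    host <- sum(p$area[p$origin == "host_unique"])
    recomb <- sum(p$area[p$origin == "recombinant_unique"])
    if (host + recomb <= 0) {
      stop("construct '", p$construct[1L],
           "': no origin-unique peak area to compare")
    }
    data.frame(construct = p$construct[1L],
               host_pct = 100 * host / (host + recomb),
               recombinant_pct = 100 * recomb / (host + recomb),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(
    list(subunit = subunit %||% "all",
         per_construct = per,
         mean_pct = mean(per$host_pct),
         sd_pct = if (nrow(per) > 1L) stats::sd(per$host_pct) else 0),
    class = "abundance_result"
  )
}

#' @export
format.abundance_result <- function(x, ...) {
  sprintf("host fraction %s: %.0f +/- %.0f%% (n = %d constructs)",
          x$subunit, x$mean_pct, x$sd_pct, nrow(x$per_construct))
}

#' @export
print.abundance_result <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Specification of expected post-translational modification sites
#'
#' The recombinant McrA of methanogenic MCR carries four characteristic
#' modifications near the active site: thioglycine, 1-N-methylhistidine,
#' 5-(S)-methylarginine, and 2-(S)-methylglutamine. [ptm_site_specs()]
#' returns the default table with standard mass deltas (methylation
#' +14.0157 Da; thioamide O->S substitution +15.9772 Da).
#'
#' @param ptm_name Modification names.
#' @param target_residue One-letter residue targeted.
#' @param expected_delta_da Expected monoisotopic mass shift in Da.
#' @return Data frame of PTM site specifications.
#' @export
ptm_site_specs <- function(
    ptm_name = c("thioglycine", "1-N-methylhistidine",
                 "5-(S)-methylarginine", "2-(S)-methylglutamine"),
    target_residue = c("G", "H", "R", "Q"),
    expected_delta_da = c(15.9772, 14.0157, 14.0157, 14.0157)) {
  stopifnot(length(ptm_name) == length(target_residue),
            length(ptm_name) == length(expected_delta_da),
            all(is.finite(expected_delta_da)), all(expected_delta_da != 0))
  data.frame(ptm_name = ptm_name, target_residue = target_residue,
             expected_delta_da = expected_delta_da,
             stringsAsFactors = FALSE)
}

#' Tabulate modification status per expected site
#'
#' Bookkeeping over an upstream search engine's identifications: for each
#' expected modification, reports `detected` if some peptide covering the
#' target residue carries a mass shift within `tolerance_da` of the
#' expected delta, `no_coverage` if no identified peptide covers the
#' target residue at all, and `not_detected` if covered but never with the
#' expected shift.
#'
#' @param identifications Data frame with columns `peptide`, `residue`
#'   (one-letter residue at the identified site), `position`, `delta_da`
#'   (`NA` for unmodified coverage rows).
#' @param specs A [ptm_site_specs()] table.
#' @param tolerance_da Matching tolerance in Da (default 0.01).
#' @return `specs` with an added `status` column.
#' @export
tabulate_ptms <- function(identifications, specs = ptm_site_specs(),
                          tolerance_da = 0.01) {
  stopifnot(is.data.frame(identifications),
            all(c("residue", "delta_da") %in% names(identifications)))
  specs$status <- vapply(seq_len(nrow(specs)), function(i) {
    cover <- identifications$residue == specs$target_residue[i]
    if (!any(cover)) return("no_coverage")
    d <- identifications$delta_da[cover]
    hit <- !is.na(d) & abs(d - specs$expected_delta_da[i]) <= tolerance_da
    if (any(hit)) "detected" else "not_detected"
  }, character(1))
  specs
}
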