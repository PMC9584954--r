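#' Pipeline configuration
#'
#' One place holding every stage's thresholds and paths, so the study
#' constants (QC 80/10, E-value 1e-5, 250 bp, 8 Angstrom, epsilon 22,500)
#' are visible and overridable together. Round-trips losslessly through
#' JSON via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param out_dir Output directory for fixtures, stage outputs, and the
#'   manifest.
#' @param seed Integer seed forwarded to the simulator.
#' @param sim A [sim_config()].
#' @param mining A [mining_config()].
#' @param mass A [mass_config()].
#' @param cofactor A [cofactor_config()].
#' @param capri A [capri_thresholds()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            sim = sim_config(seed = seed),
                            mining = mining_config(),
                            mass = mass_config(),
                            cofactor = cofactor_config(),
                            capri = capri_thresholds()) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         mining = mining, mass = mass, cofactor = cofactor,
         capri = capri),
    class = "pipeline_config"
  )
}

#' Pipeline stage names in dependency order
#' @format Character vector of the six stage names.
#' @export
PIPELINE_STAGES <- c("simulate", "scan", "masses", "chimera",
                     "cofactor", "structqc")

#' Run pipeline stages in dependency order
#'
#' Executes the requested stages against the fixture set under
#' `config$out_dir/fixtures` (written by the `simulate` stage) and
#' records a manifest: the config snapshot, per-stage output row counts,
#' and MD5 checksums of every file written. The same config and inputs
#' always yield an identical manifest apart from nothing — all stages are
#' deterministic.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of
#'   `c("simulate", "scan", "masses", "chimera", "cofactor", "structqc")`;
#'   executed in that order. An empty selection writes a manifest only.
#' @return The manifest (invisibly written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0L) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  fixtures <- file.path(config$out_dir, "fixtures")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  need_fixtures <- setdiff(stages, "simulate")
  if (length(need_fixtures) > 0L && !("simulate" %in% stages) &&
        !file.exists(file.path(fixtures, "genomes.tsv"))) {
    stop("stage '", need_fixtures[1L],
         "' requires fixtures; run the 'simulate' stage first")
  }

  manifest <- list(
    seed = config$seed,
    stages = stages,
    config = .config_snapshot(config),
    outputs = list()
  )
  record <- function(stage, paths, rows) {
    manifest$outputs[[stage]] <<- list(
      files = as.list(stats::setNames(
        unname(tools::md5sum(unlist(paths))), basename(unlist(paths)))),
      rows = rows
    )
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        g <- gen_genome_set(config$sim, fixtures)
        m <- gen_charge_series(config$sim, fixtures)
        p <- gen_peptide_areas(config$sim, fixtures)
        s <- gen_toy_structures(config$sim, fixtures)
        a <- gen_absorbance_series(config$sim, fixtures)
        record("simulate",
               c(g$paths, m$paths, p$paths, s$paths, a$paths),
               list(genomes = nrow(g$genomes),
                    features = nrow(g$features),
                    hits = nrow(g$hits),
                    planted_operons = nrow(g$truth),
                    peaks = nrow(m$peaks),
                    peptides = nrow(p$peptides)))
      },
      scan = {
        genomes <- read_genome_table(file.path(fixtures, "genomes.tsv"))
        feats <- read_features(file.path(fixtures, "features.gff3"))
        hits <- read_blast_hits(file.path(fixtures, "hits.tsv"))
        mining <- mine_operons(genomes, feats, hits, config$mining)
        paths <- write_mining_outputs(mining,
                                      file.path(config$out_dir, "scan"))
        record("scan", paths,
               list(genomes_pass_qc = nrow(mining$genomes),
                    assigned_genes = nrow(mining$assignments),
                    operons = nrow(mining$operons)))
      },
      masses = {
        peaks <- read_peak_list(file.path(fixtures, "peaks.csv"))
        if (!"z" %in% names(peaks)) {
          peaks <- infer_charges(peaks$mz, config$mass)
        }
        est <- deconvolve_series(peaks, config$mass)
        dir <- file.path(config$out_dir, "masses")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        path <- file.path(dir, "mass_estimate.tsv")
        utils::write.table(
          data.frame(mean_da = est$mean_da, sd_da = est$sd_da,
                     n_peaks = est$n_peaks),
          path, sep = "\t", quote = FALSE, row.names = FALSE)
        record("masses", path, list(estimates = 1L))
      },
      chimera = {
        pep <- read_peptide_table(file.path(fixtures, "peptides.csv"))
        pep <- classify_peptides(pep, file.path(fixtures, "host.faa"),
                                 file.path(fixtures, "recombinant.faa"))
        res <- relative_abundance(pep)
        dir <- file.path(config$out_dir, "chimera")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        path <- file.path(dir, "abundance.tsv")
        out <- res$per_construct
        out$mean_pct <- res$mean_pct
        out$sd_pct <- res$sd_pct
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record("chimera", path,
               list(constructs = nrow(res$per_construct)))
      },
      cofactor = {
        calib <- utils::read.csv(file.path(fixtures, "calibration.csv"))
        unk <- utils::read.csv(file.path(fixtures, "unknowns.csv"))
        ab <- utils::read.csv(file.path(fixtures, "absorbance.csv"))
        curve <- hplc_quantify(calib, unk$peak_area)
        conc <- f430_concentration(ab$a430, ab$pathlength_cm,
                                   ab$dilution_factor, config$cofactor)
        dir <- file.path(config$out_dir, "cofactor")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        paths <- c(curve = file.path(dir, "standard_curve.tsv"),
                   conc = file.path(dir, "concentrations.tsv"))
        utils::write.table(
          data.frame(slope = curve$slope, intercept = curve$intercept,
                     r_squared = curve$r_squared),
          paths[["curve"]], sep = "\t", quote = FALSE,
          row.names = FALSE)
        utils::write.table(
          data.frame(sample = c(unk$sample, ab$sample),
                     concentration = c(curve$concentrations, conc),
                     method = c(rep("hplc", nrow(unk)),
                                rep("absorbance", nrow(ab))),
                     wavelength_nm = config$cofactor$wavelength_nm),
          paths[["conc"]], sep = "\t", quote = FALSE,
          row.names = FALSE)
        record("cofactor", paths,
               list(standards = nrow(calib),
                    quantified = nrow(unk) + nrow(ab)))
      },
      structqc = {
        ref <- read_structure(file.path(fixtures,
                                        "synthetic_reference.pdb"))
        mod <- read_structure(file.path(fixtures,
                                        "synthetic_model.pdb"))
        ir <- irmsd(mod, ref, "A", "B",
                    config$capri$interface_cutoff)
        dir <- file.path(config$out_dir, "structqc")
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        path <- file.path(dir, "model_quality.tsv")
        utils::write.table(
          data.frame(model = "synthetic_model",
                     i_rmsd = as.numeric(ir),
                     quality = capri_quality(as.numeric(ir),
                                             config$capri),
                     n_interface_residues = attr(ir, "n_residues"),
                     n_matched_atoms = attr(ir, "n_atoms")),
          path, sep = "\t", quote = FALSE, row.names = FALSE)
        record("structqc", path, list(models = 1L))
      }
    )
  }
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.config_snapshot <- function(config) {
  list(
    mining = unclass(config$mining),
    mass = unclass(config$mass),
    cofactor = unclass(config$cofactor),
    capri = unclass(config$capri),
    sim_seed = config$sim$seed
  )
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  sim <- unclass(config$sim)
  # serialize named vectors as objects so the names survive JSON
  sim$genome$arch_probs <- as.list(sim$genome$arch_probs)
  jsonlite::write_json(
    list(out_dir = config$out_dir, seed = config$seed,
         sim = sim, mining = unclass(config$mining),
         mass = unclass(config$mass),
         cofactor = unclass(config$cofactor),
         capri = unclass(config$capri)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  drop_empty <- function(x) {
    Filter(function(v) !(is.list(v) && length(v) == 0L), as.list(x))
  }
  pipeline_config(
    out_dir = j$out_dir, seed = j$seed,
    sim = do.call(sim_config, as.list(j$sim)),
    mining = do.call(mining_config, as.list(j$mining)),
    mass = do.call(mass_config, drop_empty(j$mass)),
    cofactor = do.call(cofactor_config, as.list(j$cofactor)),
    capri = do.call(capri_thresholds, as.list(j$capri))
  )
}
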