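# Fixed per-stage seed offsets: one global seed fans out to independent
# substreams so adding a stage never perturbs another stage's data.
.STAGE_SEED_OFFSET <- c(genome = 101L, mass = 211L, peptides = 307L,
                        structures = 401L, absorbance = 503L)

.stage_seed <- function(seed, stage) {
  (as.integer(seed) + .STAGE_SEED_OFFSET[[stage]]) %% .Machine$integer.max
}

#' Simulation configuration
#'
#' Seeded configuration for every synthetic-data generator. Defaults
#' mirror the study conditions: operon gaps uniform in [20, 240] bp
#' (inside the 250 bp chaining rule), true-hit E-values far below the
#' 1e-5 cutoff and decoy E-values above it, a ~288 kDa complex observed
#' at charges 28-32, a 30% host fraction for the gamma subunit, and an
#' F430 extinction coefficient of 22,500 M^-1 cm^-1.
#'
#' @param seed Integer seed; fixes every generated byte.
#' @param genome,mass,peptides,structures,absorbance Named lists
#'   overriding per-stage defaults (see the generator documentation).
#' @return Nested list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome = list(), mass = list(),
                       peptides = list(), structures = list(),
                       absorbance = list()) {
  merge_block <- function(defaults, user) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0L) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    }
    # list-valued fields (e.g. from a JSON round-trip) collapse back to
    # named vectors
    user <- lapply(user, function(v) if (is.list(v)) unlist(v) else v)
    utils::modifyList(defaults, user)
  }
  structure(list(
    seed = as.integer(seed),
    genome = merge_block(list(
      n_genomes = 20L,
      arch_probs = c(BDCGA = 0.4, BDGA = 0.2, BGA = 0.2, BAG = 0.1,
                     unusual = 0.1),
      gap_range = c(20L, 240L),
      gene_len_range = c(500L, 1700L),
      n_decoys = 3L,
      split_prob = 0,
      split_gap_range = c(250L, 800L),
      qc_fail_frac = 0,
      true_log10e_range = c(-180, -20),
      decoy_log10e_range = c(-4.9, 0)
    ), genome),
    mass = merge_block(list(
      mass_da = 288400,
      z_range = 28:32,
      ppm_noise = 0,
      proton_mass_da = 1.007276
    ), mass),
    peptides = merge_block(list(
      host_fraction = 0.30,
      n_constructs = 3L,
      n_host = 30L,
      n_recombinant = 30L,
      n_shared = 5L,
      sigma_log = 0.5,
      subunit = "G",
      total_area = 1e6
    ), peptides),
    structures = merge_block(list(
      n_res = 30L,
      rotation_deg = 25,
      translation = c(4, -2, 3),
      perturb_sigma = 0,
      cutoff = 8.0
    ), structures),
    absorbance = merge_block(list(
      slope = 100,
      intercept = 0,
      standards = c(1, 2, 5, 10, 20),
      unknown_conc = c(2.5, 8),
      area_noise_sd = 0,
      epsilon_430 = 22500,
      planted_molar = 1e-5
    ), absorbance)
  ), class = "sim_config")
}

.random_pattern_unusual <- function() {
  repeat {
    n <- sample(1:5, 1L)
    p <- paste(sample(MCR_SUBUNITS, n, replace = FALSE), collapse = "")
    if (!(p %in% names(CANONICAL_OPERONS))) return(p)
  }
}

#' Generate a genome set with planted mcr operons
#'
#' Produces genome QC records, gene features, homology hits, and a truth
#' table. Each genome carries one planted operon whose architecture is
#' drawn from `cfg$genome$arch_probs`, with intergenic gaps drawn from
#' `gap_range`, on a random strand. Decoy genes receive hits with
#' E-values above the retention cutoff; true mcr genes receive hits from
#' two reference sources with E-values far below it. With probability
#' `split_prob` a planted operon is interrupted by a gap drawn from
#' `split_gap_range` (at or beyond the chaining threshold), and with
#' fraction `qc_fail_frac` genomes are given failing QC estimates.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; if given, writes `genomes.tsv`,
#'   `features.gff3`, `hits.tsv` (BLAST tabular), and
#'   `truth_operons.tsv`.
#' @return List: `genomes`, `features`, `hits`, `truth` data frames (and
#'   `paths` when `dir` is given).
#' @export
gen_genome_set <- function(cfg = sim_config(), dir = NULL) {
  g <- cfg$genome
  set.seed(.stage_seed(cfg$seed, "genome"))
  stopifnot(g$n_genomes >= 1L, abs(sum(g$arch_probs) - 1) < 1e-8)

  genomes <- features <- hits <- truth <- list()
  for (i in seq_len(g$n_genomes)) {
    gid <- sprintf("synth_g%03d", i)
    fails_qc <- stats::runif(1) < g$qc_fail_frac
    genomes[[i]] <- data.frame(
      genome_id = gid,
      taxonomy = paste0("d__Archaea;p__SynthPhylum;c__SynthClass;",
                        "o__SynthOrder;f__SynthFam;g__SynthGen;s__",
                        gid),
      completeness = if (fails_qc) stats::runif(1, 40, 80)
                     else stats::runif(1, 85, 100),
      contamination = if (fails_qc) stats::runif(1, 10, 30)
                      else stats::runif(1, 0, 5),
      stringsAsFactors = FALSE
    )
    arch <- sample(names(g$arch_probs), 1L, prob = g$arch_probs)
    pattern <- if (arch == "unusual") .random_pattern_unusual() else arch
    subunits <- strsplit(pattern, "")[[1L]]
    n_genes <- length(subunits)
    strand <- sample(c("+", "-"), 1L)
    contig <- paste0(gid, "_c1")

    # coordinate order: pattern is read 5'->3' on the coding strand
    coord_subunits <- if (strand == "-") rev(subunits) else subunits
    lens <- sample(g$gene_len_range[1L]:g$gene_len_range[2L], n_genes,
                   replace = TRUE)
    gaps <- if (n_genes > 1L) {
      sample(g$gap_range[1L]:g$gap_range[2L], n_genes - 1L,
             replace = TRUE)
    } else integer()
    split_here <- 0L
    if (n_genes > 1L && stats::runif(1) < g$split_prob) {
      split_here <- sample(seq_len(n_genes - 1L), 1L)
      gaps[split_here] <- sample(
        g$split_gap_range[1L]:g$split_gap_range[2L], 1L)
    }
    start <- sample(1000:5000, 1L)
    rows <- vector("list", n_genes)
    for (k in seq_len(n_genes)) {
      gene_id <- sprintf("%s_mcr%02d", gid, k)
      rows[[k]] <- data.frame(
        genome_id = gid, contig_id = contig, gene_id = gene_id,
        start = start, end = start + lens[k] - 1L, strand = strand,
        subunit = coord_subunits[k], stringsAsFactors = FALSE
      )
      if (k < n_genes) start <- start + lens[k] + gaps[k]
    }
    feat <- do.call(rbind, rows)

    # two-source homology hits with sub-threshold E-values for true genes
    for (k in seq_len(nrow(feat))) {
      for (src in c("M_maripaludis_S2", "M_acetivorans_C2A")) {
        hits[[length(hits) + 1L]] <- data.frame(
          query_source = src,
          query_subunit = feat$subunit[k],
          subject_gene_id = feat$gene_id[k],
          identity_pct = stats::runif(1, 40, 95),
          evalue = 10^stats::runif(1, g$true_log10e_range[1L],
                                   g$true_log10e_range[2L]),
          bitscore = stats::runif(1, 200, 900),
          stringsAsFactors = FALSE
        )
      }
    }
    # decoy genes: features plus above-threshold hits
    dstart <- max(feat$end) + 5000L
    for (d in seq_len(g$n_decoys)) {
      dlen <- sample(g$gene_len_range[1L]:g$gene_len_range[2L], 1L)
      did <- sprintf("%s_dec%02d", gid, d)
      feat <- rbind(feat, data.frame(
        genome_id = gid, contig_id = contig, gene_id = did,
        start = dstart, end = dstart + dlen - 1L,
        strand = sample(c("+", "-"), 1L),
        subunit = NA_character_, stringsAsFactors = FALSE
      ))
      hits[[length(hits) + 1L]] <- data.frame(
        query_source = "M_maripaludis_S2",
        query_subunit = sample(MCR_SUBUNITS, 1L),
        subject_gene_id = did,
        identity_pct = stats::runif(1, 20, 35),
        evalue = 10^stats::runif(1, g$decoy_log10e_range[1L],
                                 g$decoy_log10e_range[2L]),
        bitscore = stats::runif(1, 20, 40),
        stringsAsFactors = FALSE
      )
      dstart <- dstart + dlen + sample(500:2000, 1L)
    }
    features[[i]] <- feat
    truth[[i]] <- data.frame(
      genome_id = gid, contig_id = contig, strand = strand,
      pattern = pattern, label = classify_operon(pattern),
      n_genes = n_genes, split = split_here > 0L,
      member_gene_ids = paste(
        if (strand == "-") rev(feat$gene_id[seq_len(n_genes)])
        else feat$gene_id[seq_len(n_genes)], collapse = ","),
      fails_qc = fails_qc, stringsAsFactors = FALSE
    )
  }
  out <- list(
    genomes = do.call(rbind, genomes),
    features = do.call(rbind, features)[, c("genome_id", "contig_id",
                                            "gene_id", "start", "end",
                                            "strand")],
    hits = do.call(rbind, hits),
    truth = do.call(rbind, truth)
  )
  rownames(out$features) <- rownames(out$hits) <- NULL
  if (!is.null(dir)) out$paths <- .write_genome_fixtures(out, dir)
  out
}

.write_genome_fixtures <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genomes = file.path(dir, "genomes.tsv"),
             features = file.path(dir, "features.gff3"),
             hits = file.path(dir, "hits.tsv"),
             truth = file.path(dir, "truth_operons.tsv"))
  utils::write.table(out$genomes, paths[["genomes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  f <- out$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$contig_id,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- f$gene_id
  S4Vectors::mcols(gr)$genome_id <- f$genome_id
  rtracklayer::export(gr, paths[["features"]], format = "gff3")
  h <- out$hits
  blast <- data.frame(
    qseqid = paste0(h$query_source, "|mcr", h$query_subunit),
    sseqid = h$subject_gene_id,
    pident = round(h$identity_pct, 2),
    length = 300L, mismatch = 10L, gapopen = 1L,
    qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
    evalue = signif(h$evalue, 3), bitscore = round(h$bitscore, 1)
  )
  utils::write.table(blast, paths[["hits"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(out$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Generate a native charge-state series from a known mass
#'
#' For each charge z in `cfg$mass$z_range`, emits a peak at
#' `mz = (M + z * m_proton) / z`, optionally perturbed by Gaussian m/z
#' noise of `ppm_noise` parts per million.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; writes `peaks.csv` and
#'   `truth_mass.tsv`.
#' @return List: `peaks` (columns `mz`, `z`), `truth` (planted mass and
#'   charge window).
#' @export
gen_charge_series <- function(cfg = sim_config(), dir = NULL) {
  m <- cfg$mass
  set.seed(.stage_seed(cfg$seed, "mass"))
  if (length(m$z_range) == 0L) stop("empty charge window")
  if (any(m$z_range <= 0)) stop("charges must be positive")
  z <- sort(as.integer(m$z_range))
  mz <- (m$mass_da + z * m$proton_mass_da) / z
  if (m$ppm_noise > 0) {
    mz <- mz * (1 + stats::rnorm(length(mz), 0, m$ppm_noise * 1e-6))
  }
  out <- list(
    peaks = data.frame(mz = mz, z = z),
    truth = data.frame(mass_da = m$mass_da, z_min = min(z),
                       z_max = max(z), ppm_noise = m$ppm_noise)
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(peaks = file.path(dir, "peaks.csv"),
                   truth = file.path(dir, "truth_mass.tsv"))
    utils::write.csv(out$peaks, out$paths[["peaks"]], row.names = FALSE)
    utils::write.table(out$truth, out$paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

.random_peptide <- function(n, len_range = c(8L, 20L)) {
  vapply(seq_len(n), function(i) {
    paste(sample(names(RESIDUE_MASS_AVG),
                 sample(len_range[1L]:len_range[2L], 1L),
                 replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate peptide peak areas around a planted host fraction
#'
#' Builds host-unique, recombinant-unique, and shared peptide sequences,
#' assembles host and recombinant proteome sequences that contain them
#' (so substring classification recovers the planted origins), and draws
#' per-peptide areas from a lognormal distribution whose expected sums
#' give the planted host fraction. With `sigma_log = 0` the realized
#' fraction is exact.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; writes `peptides.csv`, `host.faa`,
#'   `recombinant.faa`, `truth_peptides.tsv`.
#' @return List: `peptides` (construct, subunit, peptide, area, with the
#'   planted `origin`), `host_proteome`, `recombinant_proteome`
#'   (character vectors), `truth`.
#' @export
gen_peptide_areas <- function(cfg = sim_config(), dir = NULL) {
  p <- cfg$peptides
  set.seed(.stage_seed(cfg$seed, "peptides"))
  stopifnot(p$host_fraction >= 0, p$host_fraction <= 1)
  if (p$n_host < 1L || p$n_recombinant < 1L) {
    stop("need at least one peptide on each side")
  }
  host_pep <- .random_peptide(p$n_host)
  recomb_pep <- .random_peptide(p$n_recombinant)
  shared_pep <- .random_peptide(p$n_shared)
  linker <- function() .random_peptide(1L, c(3L, 6L))
  assemble <- function(unique_pep) {
    paste(vapply(c(unique_pep, shared_pep),
                 function(x) paste0(x, linker()), character(1)),
          collapse = "")
  }
  host_prot <- assemble(host_pep)
  recomb_prot <- assemble(recomb_pep)

  draw_areas <- function(n, total_share) {
    mu <- log(total_share * p$total_area / n) - p$sigma_log^2 / 2
    stats::rlnorm(n, meanlog = mu, sdlog = p$sigma_log)
  }
  obs <- list()
  for (con in sprintf("construct_%d", seq_len(p$n_constructs))) {
    obs[[con]] <- data.frame(
      construct = con,
      subunit = p$subunit,
      peptide = c(host_pep, recomb_pep, shared_pep),
      area = c(draw_areas(p$n_host, p$host_fraction),
               draw_areas(p$n_recombinant, 1 - p$host_fraction),
               draw_areas(max(p$n_shared, 1L), 0.2)[
                 seq_len(p$n_shared)]),
      origin = c(rep("host_unique", p$n_host),
                 rep("recombinant_unique", p$n_recombinant),
                 rep("shared", p$n_shared)),
      stringsAsFactors = FALSE
    )
  }
  peptides <- do.call(rbind, obs)
  rownames(peptides) <- NULL
  out <- list(
    peptides = peptides,
    host_proteome = c(McrG_host = host_prot),
    recombinant_proteome = c(McrG_recombinant = recomb_prot),
    truth = data.frame(host_fraction = p$host_fraction,
                       sigma_log = p$sigma_log,
                       n_constructs = p$n_constructs)
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(peptides = file.path(dir, "peptides.csv"),
                   host = file.path(dir, "host.faa"),
                   recombinant = file.path(dir, "recombinant.faa"),
                   truth = file.path(dir, "truth_peptides.tsv"))
    utils::write.csv(peptides[, c("construct", "subunit", "peptide",
                                  "area")],
                     out$paths[["peptides"]], row.names = FALSE)
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(out$host_proteome), out$paths[["host"]])
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(out$recombinant_proteome),
      out$paths[["recombinant"]])
    utils::write.table(out$truth, out$paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

# --- independent I_rmsd oracle -------------------------------------------
# Deliberately different route from irmsd(): O(n^2) distance loops for the
# interface and quaternion-eigenvalue superposition instead of SVD Kabsch.

.oracle_interface <- function(s, group1, group2, cutoff) {
  a1 <- s[s$chain %in% group1 & s$is_heavy, , drop = FALSE]
  a2 <- s[s$chain %in% group2 & s$is_heavy, , drop = FALSE]
  keys <- character()
  for (i in seq_len(nrow(a1))) {
    for (j in seq_len(nrow(a2))) {
      d <- sqrt((a1$x[i] - a2$x[j])^2 + (a1$y[i] - a2$y[j])^2 +
                  (a1$z[i] - a2$z[j])^2)
      if (d <= cutoff) {
        keys <- c(keys, paste(a1$chain[i], a1$resno[i], sep = "\r"),
                  paste(a2$chain[j], a2$resno[j], sep = "\r"))
      }
    }
  }
  unique(keys)
}

.oracle_superpose_rmsd <- function(p, q) {
  pc <- sweep(p, 2L, colMeans(p))
  qc <- sweep(q, 2L, colMeans(q))
  m <- crossprod(pc, qc)
  k <- matrix(c(
    m[1,1] + m[2,2] + m[3,3], m[2,3] - m[3,2], m[3,1] - m[1,3],
    m[1,2] - m[2,1],
    m[2,3] - m[3,2], m[1,1] - m[2,2] - m[3,3], m[1,2] + m[2,1],
    m[1,3] + m[3,1],
    m[3,1] - m[1,3], m[1,2] + m[2,1], -m[1,1] + m[2,2] - m[3,3],
    m[2,3] + m[3,2],
    m[1,2] - m[2,1], m[1,3] + m[3,1], m[2,3] + m[3,2],
    -m[1,1] - m[2,2] + m[3,3]), 4L, 4L, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  e <- (sum(pc^2) + sum(qc^2) - 2 * lambda) / nrow(p)
  sqrt(max(e, 0))
}

.oracle_irmsd <- function(model, reference, group1, group2, cutoff) {
  ikey <- .oracle_interface(reference, group1, group2, cutoff)
  sel <- function(s) {
    a <- s[s$is_heavy &
             paste(s$chain, s$resno, sep = "\r") %in% ikey, ,
           drop = FALSE]
    a[order(a$chain, a$resno, a$elety), , drop = FALSE]
  }
  am <- sel(model); ar <- sel(reference)
  stopifnot(identical(paste(am$chain, am$resno, am$elety),
                      paste(ar$chain, ar$resno, ar$elety)))
  .oracle_superpose_rmsd(.coords(am), .coords(ar))
}

.rotation_matrix <- function(angle_deg, axis = c(0, 0, 1)) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  c <- cos(a); s <- sin(a)
  outer(u, u) * (1 - c) + diag(3) * c +
    matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L) * s
}

#' Generate a toy two-chain complex and a perturbed docking model
#'
#' Builds a two-chain reference structure with a contact interface (two
#' backbone strands running side by side ~5 Angstrom apart, four heavy
#' atoms plus one amide hydrogen per residue), then derives a model by
#' applying a global rigid transform (`rotation_deg` about a random axis
#' plus `translation`) and, optionally, per-atom Gaussian noise of
#' `perturb_sigma` Angstrom. The truth table carries the I_rmsd of the
#' model computed by an independent oracle (O(n^2) interface scan plus
#' quaternion superposition).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; writes `reference.pdb` (synthetic),
#'   `model.pdb` (synthetic), `truth_structures.tsv`.
#' @return List: `reference`, `model` (`pdb_structure`), `truth`.
#' @export
gen_toy_structures <- function(cfg = sim_config(), dir = NULL) {
  st <- cfg$structures
  set.seed(.stage_seed(cfg$seed, "structures"))
  n <- as.integer(st$n_res)
  if (n < 4L) stop("need >= 4 residues per chain")

  build_chain <- function(chain, x0, y0) {
    rows <- list()
    resnames <- sample(c("ALA", "GLY", "LEU", "SER", "VAL", "THR",
                         "PHE", "ASP", "LYS", "ARG"), n, replace = TRUE)
    for (i in seq_len(n)) {
      ca <- c(x0 + 3.8 * i + stats::rnorm(1, 0, 0.2),
              y0 + stats::rnorm(1, 0, 0.3),
              stats::rnorm(1, 0, 0.3))
      atoms <- rbind(
        N  = ca + c(-1.2,  0.8, 0.3),
        CA = ca,
        C  = ca + c( 1.3,  0.6, -0.2),
        O  = ca + c( 1.5,  1.8, -0.3),
        H  = ca + c(-1.6,  1.7, 0.5)
      )
      rows[[i]] <- data.frame(
        record = "ATOM", chain = chain, resno = i, resid = resnames[i],
        elety = rownames(atoms),
        element = c("N", "C", "C", "O", "H"),
        x = atoms[, 1L], y = atoms[, 2L], z = atoms[, 3L],
        occupancy = 1, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  }
  # chain B runs alongside the second half of chain A: a partial interface
  ref <- rbind(build_chain("A", 0, 0),
               build_chain("B", 3.8 * n / 2, 5.0))
  ref$is_heavy <- !(ref$element %in% c("H", "D"))
  rownames(ref) <- NULL
  class(ref) <- c("pdb_structure", "data.frame")

  axis <- stats::rnorm(3)
  rot <- .rotation_matrix(st$rotation_deg, axis)
  xyz <- .coords(ref)
  xyz_m <- sweep(tcrossprod(xyz, rot), 2L, st$translation, "+")
  if (st$perturb_sigma > 0) {
    xyz_m <- xyz_m + matrix(stats::rnorm(length(xyz_m), 0,
                                         st$perturb_sigma),
                            ncol = 3L)
  }
  model <- ref
  model$x <- xyz_m[, 1L]; model$y <- xyz_m[, 2L]; model$z <- xyz_m[, 3L]

  truth_irmsd <- .oracle_irmsd(model, ref, "A", "B", st$cutoff)
  out <- list(
    reference = ref, model = model,
    truth = data.frame(i_rmsd = truth_irmsd,
                       perturb_sigma = st$perturb_sigma,
                       rotation_deg = st$rotation_deg)
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(reference = file.path(dir, "synthetic_reference.pdb"),
                   model = file.path(dir, "synthetic_model.pdb"),
                   truth = file.path(dir, "truth_structures.tsv"))
    write_structure_pdb(ref, out$paths[["reference"]])
    write_structure_pdb(model, out$paths[["model"]])
    utils::write.table(out$truth, out$paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write a structure as PDB-format text
#'
#' @param s A `pdb_structure`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_structure_pdb <- function(s, path) {
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    s$record, seq_len(nrow(s)),
    ifelse(nchar(s$elety) < 4L, paste0(" ", s$elety), s$elety),
    s$resid, s$chain, s$resno, s$x, s$y, s$z, s$occupancy, 0,
    s$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate absorbance and HPLC calibration fixtures
#'
#' Calibration peak areas follow the planted line
#' `area = slope * conc + intercept` with optional Gaussian noise;
#' unknowns are placed on the same line. The absorbance table encodes a
#' planted molar concentration through the configured extinction
#' coefficient.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; writes `calibration.csv`,
#'   `unknowns.csv`, `absorbance.csv`, `truth_cofactor.tsv`.
#' @return List: `calibration`, `unknowns`, `absorbance`, `truth`.
#' @export
gen_absorbance_series <- function(cfg = sim_config(), dir = NULL) {
  ab <- cfg$absorbance
  set.seed(.stage_seed(cfg$seed, "absorbance"))
  if (length(ab$standards) < 2L) stop("need >= 2 calibration standards")
  calib <- data.frame(
    concentration = ab$standards,
    peak_area = ab$slope * ab$standards + ab$intercept +
      stats::rnorm(length(ab$standards), 0, ab$area_noise_sd)
  )
  unknowns <- data.frame(
    sample = sprintf("unknown_%d", seq_along(ab$unknown_conc)),
    peak_area = ab$slope * ab$unknown_conc + ab$intercept
  )
  absorbance <- data.frame(
    sample = "purified_complex",
    a430 = ab$epsilon_430 * ab$planted_molar,
    pathlength_cm = 1.0, dilution_factor = 1.0
  )
  out <- list(
    calibration = calib, unknowns = unknowns, absorbance = absorbance,
    truth = data.frame(slope = ab$slope, intercept = ab$intercept,
                       unknown_conc = paste(ab$unknown_conc,
                                            collapse = ","),
                       planted_molar = ab$planted_molar)
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(calibration = file.path(dir, "calibration.csv"),
                   unknowns = file.path(dir, "unknowns.csv"),
                   absorbance = file.path(dir, "absorbance.csv"),
                   truth = file.path(dir, "truth_cofactor.tsv"))
    utils::write.csv(calib, out$paths[["calibration"]],
                     row.names = FALSE)
    utils::write.csv(unknowns, out$paths[["unknowns"]],
                     row.names = FALSE)
    utils::write.csv(absorbance, out$paths[["absorbance"]],
                     row.names = FALSE)
    utils::write.table(out$truth, out$paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
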