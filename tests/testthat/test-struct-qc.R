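two_residue_structure <- function(sep) {
  txt <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"),
    pdb_line(2, "CB", "ALA", "A", 1, 1.5, 0, 0, element = "C"),
    pdb_line(3, "CA", "GLY", "B", 1, 1.5 + sep, 0, 0, element = "C"),
    "END")
  read_structure(txt)
}

test_that("PDB parsing flags hydrogens, validates coordinates, and keeps
           the top-occupancy altloc", {
  txt <- c(pdb_line(1, "CA", "ALA", "A", 1, 1.0, 2.0, 3.0,
                    element = "C"),
           pdb_line(2, "H", "ALA", "A", 1, 1.5, 2.5, 3.5,
                    element = "H"))
  s <- read_structure(txt)
  expect_equal(nrow(s), 2L)
  expect_identical(s$is_heavy, c(TRUE, FALSE))
  expect_equal(s$x[1], 1.0)
  bad <- sub("   1.000", "  1.0e.0", txt[1], fixed = TRUE)
  expect_error(read_structure(c(txt[2], bad)), "line 2")
  # altloc: highest occupancy conformer survives
  alt <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C",
                    occ = 0.4, alt = "A"),
           pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9, element = "C",
                    occ = 0.6, alt = "B"))
  s2 <- read_structure(alt)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$x, 9)
})

test_that("interface membership is inclusive at the 8 A boundary", {
  close <- interface_residues(two_residue_structure(7.9), "A", "B")
  expect_equal(nrow(close), 2L)
  boundary <- interface_residues(two_residue_structure(8.0), "A", "B")
  expect_equal(nrow(boundary), 2L)
  apart <- interface_residues(two_residue_structure(8.1), "A", "B")
  expect_equal(nrow(apart), 0L)
  expect_error(interface_residues(two_residue_structure(5), "A", "A"),
               "disjoint")
  expect_error(
    interface_residues(two_residue_structure(5), character(), "B"),
    "nonempty")
})

test_that("interface detection equals the all-pairs scan and is
           symmetric and cutoff-monotone", {
  for (seed in 1:5) {
    sim <- gen_toy_structures(sim_config(
      seed = seed, structures = list(n_res = 40L)))
    s <- sim$reference
    got <- interface_residues(s, "A", "B")
    keys <- sort(paste0(got$chain, ":", got$resno))
    expect_identical(keys, oracle_interface_keys(s, "A", "B", 8))
    flipped <- interface_residues(s, "B", "A")
    expect_identical(sort(paste0(flipped$chain, ":", flipped$resno)),
                     keys)
    wider <- interface_residues(s, "A", "B", cutoff = 12)
    expect_true(all(keys %in% paste0(wider$chain, ":", wider$resno)))
  }
})

test_that("Kabsch superposition is exact on rigidly moved copies and
           always proper", {
  set.seed(23)
  p <- matrix(stats::rnorm(60, sd = 8), ncol = 3L)
  idfit <- kabsch_superpose(p, p)
  expect_equal(idfit$rmsd, 0, tolerance = 1e-9)
  expect_equal(idfit$rotation, diag(3), tolerance = 1e-9)
  # 37 degree rotation + translation (5, -3, 2)
  a <- 37 * pi / 180
  rot37 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L)
  q <- sweep(tcrossprod(p, rot37), 2L, c(5, -3, 2), "+")
  fit <- kabsch_superpose(p, q)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # reflection-degenerate input: mirrored copy still yields det +1
  mfit <- kabsch_superpose(p, p %*% diag(c(-1, 1, 1)))
  expect_equal(det(mfit$rotation), 1, tolerance = 1e-9)
  expect_gt(mfit$rmsd, 0)
  # degenerate geometry is refused
  line <- cbind(1:10, 2 * (1:10), -1:-10 * 3)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(p[1:2, ], p[1:2, ]), ">= 3")
})

test_that("a displaced-atom RMSD matches the numerical-minimization
           oracle", {
  set.seed(41)
  p <- matrix(stats::rnorm(45, sd = 6), ncol = 3L)
  q <- p
  q[1L, ] <- q[1L, ] + c(2, -1, 0.5)
  fit <- kabsch_superpose(p, q)
  expect_equal(fit$rmsd, oracle_superpose_rmsd(p, q), tolerance = 1e-6)
})

test_that("I_rmsd vanishes under rigid motion and matches the two-step
           oracle under perturbation", {
  sim <- gen_toy_structures(sim_config(seed = 3))
  ref <- sim$reference
  expect_equal(as.numeric(irmsd(ref, ref, "A", "B")), 0,
               tolerance = 1e-9)
  set.seed(8)
  for (i in 1:3) {
    moved <- apply_rigid(ref, random_rigid_transform(struct_coords(ref)))
    expect_lt(as.numeric(irmsd(moved, ref, "A", "B")), 1e-6)
  }
  pert <- gen_toy_structures(sim_config(
    seed = 13, structures = list(perturb_sigma = 0.8)))
  got <- as.numeric(irmsd(pert$model, pert$reference, "A", "B"))
  expect_equal(got,
               oracle_two_step_irmsd(pert$model, pert$reference,
                                     "A", "B", 8),
               tolerance = 1e-6)
  expect_equal(got, pert$truth$i_rmsd, tolerance = 1e-6)
})

test_that("missing atoms fall back to the matched subset with a
           warning", {
  sim <- gen_toy_structures(sim_config(
    seed = 5, structures = list(perturb_sigma = 0.3)))
  model <- sim$model
  iface <- interface_residues(sim$reference, "A", "B")
  in_iface <- paste(model$chain, model$resno) %in%
    paste(iface$chain, iface$resno)
  drop_idx <- which(model$is_heavy & in_iface)[c(1, 5, 9)]
  model <- model[-drop_idx, , drop = FALSE]
  expect_warning(got <- irmsd(model, sim$reference, "A", "B"),
                 "unmatched")
  expect_true(is.finite(as.numeric(got)))
  tiny <- sim$reference[1:4, , drop = FALSE]
  expect_error(suppressWarnings(irmsd(tiny, sim$reference, "A", "B")),
               "fewer than 3|no heavy atoms|nonempty")
})

test_that("CAPRI classes bin I_rmsd with boundaries in the lower class", {
  expect_identical(capri_quality(c(0.5, 1.848, 3.0, 5.869)),
                   c("high", "medium", "acceptable", "incorrect"))
  expect_identical(capri_quality(c(0.99, 1.0, 1.99, 2.0, 3.99, 4.0)),
                   c("high", "medium", "medium", "acceptable",
                     "acceptable", "incorrect"))
  expect_error(capri_quality(-0.1), "nonnegative")
  expect_error(capri_thresholds(high = 2, medium = 1), "increasing")
  # monotone step function
  xs <- seq(0, 6, by = 0.01)
  lv <- match(capri_quality(xs),
              c("high", "medium", "acceptable", "incorrect"))
  expect_true(all(diff(lv) >= 0))
})

test_that("ligand-proximal residues match the all-pairs oracle", {
  sim <- gen_toy_structures(sim_config(seed = 21,
                                       structures = list(n_res = 15L)))
  s <- sim$reference
  lig_xyz <- colMeans(struct_coords(s[s$chain == "B", ]))
  lig <- data.frame(
    record = "HETATM", chain = "L", resno = 1L, resid = "F43",
    elety = c("NI", "C1", "C2"),
    element = c("NI", "C", "C"),
    x = lig_xyz[1] + c(0, 1.4, -1.4), y = lig_xyz[2] + c(0, 0.7, 0.7),
    z = lig_xyz[3] + c(0, 0, 0.5), occupancy = 1,
    is_heavy = TRUE, stringsAsFactors = FALSE)
  full <- rbind(as.data.frame(s), lig)
  class(full) <- c("pdb_structure", "data.frame")
  got <- ligand_proximal_residues(full, "F43", cutoff = 8)
  # explicit all-pairs scan over protein heavy atoms
  prot <- full[full$resid != "F43" & full$is_heavy, ]
  want <- unique(do.call(rbind, lapply(seq_len(nrow(prot)), function(i) {
    d <- sqrt((prot$x[i] - lig$x)^2 + (prot$y[i] - lig$y)^2 +
                (prot$z[i] - lig$z)^2)
    if (min(d) <= 8) prot[i, c("chain", "resno", "resid")] else NULL
  })))
  want <- want[order(want$chain, want$resno), ]
  expect_equal(got, want, ignore_attr = TRUE)
  expect_gt(nrow(got), 0L)
  expect_error(ligand_proximal_residues(full, "XYZ"), "matched no")
})
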