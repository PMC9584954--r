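# Independent oracles, implemented with different algorithms from the
# package paths they check.

# Brute-force operon grouping: start with singleton clusters and merge any
# two genes that are mutually adjacent (no third mcr gene between them) with
# an intergenic gap below the threshold, iterating to a fixpoint.
oracle_operons <- function(assignments, features, max_gap_bp = 250) {
  df <- merge(assignments, features, by = "gene_id")
  out <- list()
  for (grp in split(df, list(df$genome_id, df$contig_id, df$strand),
                    drop = TRUE)) {
    n <- nrow(grp)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i == j || comp[i] == comp[j]) next
          lo <- if (grp$start[i] < grp$start[j]) i else j
          hi <- if (lo == i) j else i
          between <- grp$start > grp$start[lo] & grp$start < grp$start[hi]
          between[c(lo, hi)] <- FALSE
          if (any(between)) next
          gap <- max(grp$start[hi] - grp$end[lo] - 1L, 0L)
          if (gap < max_gap_bp) {
            comp[comp == comp[hi]] <- comp[lo]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    for (cl in unique(comp)) {
      members <- grp[comp == cl, , drop = FALSE]
      members <- members[order(members$start), , drop = FALSE]
      if (members$strand[1L] == "-") {
        members <- members[rev(seq_len(nrow(members))), , drop = FALSE]
      }
      out[[length(out) + 1L]] <- data.frame(
        genome_id = members$genome_id[1L],
        contig_id = members$contig_id[1L],
        strand = members$strand[1L],
        member_gene_ids = paste(members$gene_id, collapse = ","),
        pattern = paste(members$subunit, collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out[order(out$genome_id, out$contig_id, out$member_gene_ids), ,
      drop = FALSE]
}

# Exhaustive stoichiometry enumeration by recursive loops.
oracle_stoichiometry <- function(observed, components, tolerance,
                                 group_sums = NULL) {
  n <- nrow(components)
  results <- list()
  recurse <- function(counts) {
    k <- length(counts)
    if (k == n) {
      if (!is.null(group_sums)) {
        for (g in names(group_sums)) {
          members <- which(!is.na(components$group) &
                             components$group == g)
          if (sum(counts[members]) != group_sums[[g]]) return(invisible())
        }
      }
      total <- sum(counts * components$mass_da)
      if (abs(observed - total) <= tolerance) {
        results[[length(results) + 1L]] <<-
          c(counts, total = total, delta = observed - total)
      }
      return(invisible())
    }
    for (c_next in components$min_count[k + 1L]:components$max_count[k + 1L]) {
      recurse(c(counts, c_next))
    }
  }
  recurse(integer())
  if (length(results) == 0L) {
    return(matrix(numeric(), ncol = n + 2L,
                  dimnames = list(NULL, c(components$name, "total",
                                          "delta"))))
  }
  m <- do.call(rbind, results)
  colnames(m) <- c(components$name, "total", "delta")
  ord <- do.call(order, c(list(abs(m[, "delta"])),
                          as.data.frame(m[, components$name,
                                          drop = FALSE])))
  m[ord, , drop = FALSE]
}

# Rigid-body superposition RMSD by direct numerical minimization over
# Euler angles and translation.
oracle_superpose_rmsd <- function(p, q) {
  rot_euler <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    rz %*% ry %*% rx
  }
  objective <- function(par) {
    r <- rot_euler(par[1:3])
    fitted <- sweep(tcrossprod(p, r), 2L, par[4:6], "+")
    sqrt(mean(rowSums((fitted - q)^2)))
  }
  best <- Inf
  set.seed(42)
  starts <- rbind(rep(0, 6),
                  matrix(stats::runif(5 * 6, -pi, pi), ncol = 6))
  starts[, 4:6] <- 0
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], objective, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15))
    best <- min(best, fit$value)
  }
  best
}

# All-pairs interface scan with explicit loops.
oracle_interface_keys <- function(s, group1, group2, cutoff) {
  a1 <- s[s$chain %in% group1 & s$is_heavy, , drop = FALSE]
  a2 <- s[s$chain %in% group2 & s$is_heavy, , drop = FALSE]
  keys <- character()
  for (i in seq_len(nrow(a1))) {
    for (j in seq_len(nrow(a2))) {
      d <- sqrt((a1$x[i] - a2$x[j])^2 + (a1$y[i] - a2$y[j])^2 +
                  (a1$z[i] - a2$z[j])^2)
      if (d <= cutoff) {
        keys <- c(keys, paste0(a1$chain[i], ":", a1$resno[i]),
                  paste0(a2$chain[j], ":", a2$resno[j]))
      }
    }
  }
  sort(unique(keys))
}

# Two-step I_rmsd oracle: explicit interface list then explicit
# superposition by numerical minimization.
oracle_two_step_irmsd <- function(model, reference, group1, group2,
                                  cutoff) {
  keys <- oracle_interface_keys(reference, group1, group2, cutoff)
  sel <- function(s) {
    a <- s[s$is_heavy &
             paste0(s$chain, ":", s$resno) %in% keys, , drop = FALSE]
    a[order(a$chain, a$resno, a$elety), , drop = FALSE]
  }
  am <- sel(model); ar <- sel(reference)
  oracle_superpose_rmsd(as.matrix(am[, c("x", "y", "z")]),
                        as.matrix(ar[, c("x", "y", "z")]))
}

random_rigid_transform <- function(coords) {
  a <- stats::runif(3, -pi, pi)
  cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  r <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3) %*%
    matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3) %*%
    matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  sweep(tcrossprod(coords, r), 2L, stats::runif(3, -20, 20), "+")
}

apply_rigid <- function(s, coords) {
  s$x <- coords[, 1L]; s$y <- coords[, 2L]; s$z <- coords[, 3L]
  s
}

struct_coords <- function(s) as.matrix(s[, c("x", "y", "z")])

# Minimal PDB text builder for parser tests.
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     element = substr(name, 1, 1), record = "ATOM",
                     occ = 1, alt = " ") {
  name4 <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resn, chain, resno,
          x, y, z, occ, 0, element)
}
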