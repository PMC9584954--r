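make_features <- function(starts, ends, strand = "+",
                          genome = "g1", contig = "c1") {
  data.frame(
    genome_id = genome, contig_id = contig,
    gene_id = sprintf("%s_gene%02d", genome, seq_along(starts)),
    start = starts, end = ends, strand = strand,
    stringsAsFactors = FALSE
  )
}

make_assignments <- function(features, subunits) {
  data.frame(gene_id = features$gene_id, subunit = subunits,
             best_bitscore = 500, best_evalue = 1e-50,
             stringsAsFactors = FALSE)
}

test_that("genome QC applies strict completeness/contamination bounds", {
  genomes <- data.frame(
    genome_id = c("a", "b", "c", "d", "e"),
    completeness = c(85, 80.0, 95, 81, NA),
    contamination = c(5, 5, 10.0, 9.99, 1)
  )
  expect_warning(kept <- qc_filter(genomes), "rejected")
  expect_identical(kept$genome_id, c("a", "d"))
})

test_that("E-value filtering excludes only values strictly above 1e-5", {
  hits <- data.frame(evalue = c(1e-6, 2e-5, 1e-5),
                     subject_gene_id = c("x", "y", "z"))
  expect_identical(filter_hits(hits)$subject_gene_id, c("x", "z"))
  expect_error(filter_hits(data.frame(evalue = -1)), "negative")
})

test_that("subunit assignment takes best bitscore with deterministic ties", {
  hits <- data.frame(
    subject_gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    query_subunit   = c("A", "G", "B", "B", "D", "C"),
    query_source    = c("s1", "s1", "s1", "s2", "s1", "s1"),
    bitscore        = c(500, 60, 300, 280, 100, 100),
    evalue          = c(1e-50, 1e-10, 1e-40, 1e-38, 1e-20, 1e-20),
    stringsAsFactors = FALSE
  )
  asg <- assign_subunits(hits)
  expect_identical(asg$subunit[asg$gene_id == "g1"], "A")
  expect_identical(asg$subunit[asg$gene_id == "g2"], "B")
  # equal bitscore and evalue: alphabetical subunit wins
  expect_identical(asg$subunit[asg$gene_id == "g3"], "C")
  expect_equal(nrow(asg), 3L)
})

test_that("a full BDCGA cluster with sub-threshold gaps is one operon", {
  feats <- make_features(c(100, 1600, 2200, 2900, 3700),
                         c(1500, 2100, 2800, 3600, 5300))
  asg <- make_assignments(feats, c("B", "D", "C", "G", "A"))
  ops <- call_operons(asg, feats)
  expect_equal(nrow(ops), 1L)
  expect_identical(ops$pattern, "BDCGA")
  expect_identical(ops$label, "mcrBDCGA")
})

test_that("the 250 bp rule is strict: gap 249 merges, gap 250 splits", {
  merged <- call_operons(
    make_assignments(make_features(c(100, 1250), c(1000, 2000)),
                     c("B", "G")),
    make_features(c(100, 1250), c(1000, 2000)))
  expect_equal(nrow(merged), 1L)
  split <- call_operons(
    make_assignments(make_features(c(100, 1251), c(1000, 2000)),
                     c("B", "G")),
    make_features(c(100, 1251), c(1000, 2000)))
  expect_equal(nrow(split), 2L)
})

test_that("minus-strand operons read 5'->3' on the coding strand", {
  feats <- make_features(c(100, 1800, 2600), c(1700, 2500, 4100),
                         strand = "-")
  asg <- make_assignments(feats, c("A", "G", "B"))
  ops <- call_operons(asg, feats)
  expect_identical(ops$pattern, "BGA")
  expect_identical(ops$label, "mcrBGA")
  expect_identical(
    ops$member_gene_ids,
    paste(rev(feats$gene_id), collapse = ","))
  # agrees with the brute-force grouping oracle
  oracle <- oracle_operons(asg, feats)
  expect_identical(ops$pattern, oracle$pattern)
})

test_that("overlapping genes merge with a warning rather than split", {
  feats <- make_features(c(100, 900), c(1000, 1900))
  asg <- make_assignments(feats, c("B", "G"))
  expect_warning(ops <- call_operons(asg, feats), "overlap")
  expect_equal(nrow(ops), 1L)
})

test_that("architecture classification is exact-match with unusual fallback", {
  expect_identical(
    classify_operon(c("BDCGA", "BDGA", "BGA", "BAG")),
    c("mcrBDCGA", "mcrBDGA", "mcrBGA", "mcrBAG"))
  expect_identical(classify_operon(c("GBA", "A", "BGABGA")),
                   rep("unusual", 3L))
  expect_error(classify_operon("BXA"), "alphabet|within")
})

test_that("genome summaries count complete sets and mcr copies", {
  feats <- rbind(
    make_features(c(100, 1600, 2200, 2900, 3700),
                  c(1500, 2100, 2800, 3600, 5300), genome = "g1"),
    make_features(c(100, 1600, 2200), c(1500, 2100, 3600),
                  genome = "g2", contig = "c2"))
  asg <- rbind(make_assignments(feats[1:5, ], c("B", "D", "C", "G", "A")),
               make_assignments(feats[6:8, ], c("B", "G", "A")))
  genomes <- data.frame(genome_id = c("g1", "g2", "g3"),
                        completeness = 95, contamination = 1,
                        category = c("methanogen", "ANME-1", "unknown"))
  ops <- call_operons(asg, feats)
  smry <- summarize_genomes(ops, asg, feats, genomes)
  expect_identical(smry$has_complete_set, c(TRUE, TRUE, FALSE))
  expect_identical(smry$mcr_copy_count, c(1L, 1L, 0L))
  expect_identical(smry$operon_labels[1:2], c("mcrBDCGA", "mcrBGA"))
  # two-copy genome: one mcrBDCGA plus one mcrBGA
  feats2 <- rbind(feats[1:5, ],
                  make_features(c(9000, 10600, 11200),
                                c(10500, 11100, 12600), genome = "g1"))
  feats2$gene_id[6:8] <- paste0("g1_copy2_", 1:3)
  asg2 <- rbind(asg[1:5, ],
                data.frame(gene_id = feats2$gene_id[6:8],
                           subunit = c("B", "G", "A"),
                           best_bitscore = 500, best_evalue = 1e-50))
  smry2 <- summarize_genomes(call_operons(asg2, feats2), asg2, feats2,
                             genomes[1, ])
  expect_identical(smry2$mcr_copy_count, 2L)
  expect_identical(smry2$operon_labels, "mcrBDCGA,mcrBGA")
  expect_error(
    summarize_genomes(data.frame(genome_id = "nope", pattern = "BGA",
                                 label = "mcrBGA"),
                      asg, feats, genomes),
    "unknown genome_id")
})

test_that("genes with only B and G assignments lack the complete set", {
  feats <- make_features(c(100, 1600), c(1500, 2100))
  asg <- make_assignments(feats, c("B", "G"))
  genomes <- data.frame(genome_id = "g1", completeness = 95,
                        contamination = 1)
  smry <- summarize_genomes(call_operons(asg, feats), asg, feats, genomes)
  expect_false(smry$has_complete_set)
})

test_that("raising the gap threshold never shrinks operons and lowering
           the E-value cutoff never adds assignments", {
  set.seed(31)
  sim <- gen_genome_set(sim_config(seed = 31,
                                   genome = list(n_genomes = 12L,
                                                 split_prob = 0.5)))
  hits <- sim$hits
  for (em in c(1e-20, 1e-10, 1e-5)) {
    n_low <- nrow(assign_subunits(
      filter_hits(hits, mining_config(max_evalue = em / 100))))
    n_high <- nrow(assign_subunits(
      filter_hits(hits, mining_config(max_evalue = em))))
    expect_lte(n_low, n_high)
  }
  asg <- assign_subunits(filter_hits(hits))
  sizes <- function(gap) {
    ops <- call_operons(asg, sim$features, mining_config(max_gap_bp = gap))
    sort(ops$n_genes, decreasing = TRUE)
  }
  s250 <- sizes(250); s1000 <- sizes(1000)
  expect_lte(length(s1000), length(s250))
  expect_gte(max(s1000), max(s250))
  expect_gte(sum(s1000^2), sum(s250^2))
})

test_that("mirroring a contig and flipping strands preserves patterns", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:5, 1L)
    lens <- sample(500:1700, n, replace = TRUE)
    gaps <- sample(20:240, max(n - 1L, 1L), replace = TRUE)
    starts <- cumsum(c(1000L, lens[-n] + gaps[seq_len(n - 1L)]))
    ends <- starts + lens - 1L
    strand <- sample(c("+", "-"), 1L)
    feats <- make_features(starts, ends, strand = strand)
    asg <- make_assignments(feats, sample(c("A", "B", "C", "D", "G"), n))
    contig_len <- max(ends) + 1000L
    mirrored <- feats
    mirrored$start <- contig_len - ends + 1L
    mirrored$end <- contig_len - starts + 1L
    mirrored$strand <- if (strand == "+") "-" else "+"
    p1 <- sort(call_operons(asg, feats)$pattern)
    p2 <- sort(call_operons(asg, mirrored)$pattern)
    expect_identical(p1, p2)
  }
})

test_that("mining IO round-trips through GFF3, BLAST tabular and TSV", {
  dir <- withr::local_tempdir()
  sim <- gen_genome_set(sim_config(seed = 9,
                                   genome = list(n_genomes = 4L)), dir)
  genomes <- read_genome_table(sim$paths[["genomes"]])
  expect_identical(genomes$genome_id, sim$genomes$genome_id)
  feats <- read_features(sim$paths[["features"]])
  expect_setequal(feats$gene_id, sim$features$gene_id)
  expect_identical(
    feats$start[match(sim$features$gene_id, feats$gene_id)],
    sim$features$start)
  hits <- read_blast_hits(sim$paths[["hits"]])
  expect_equal(nrow(hits), nrow(sim$hits))
  expect_setequal(unique(hits$query_subunit),
                  unique(sim$hits$query_subunit))
  mining <- mine_operons(genomes, feats, hits)
  expect_identical(sort(mining$operons$pattern), sort(sim$truth$pattern))
  paths <- write_mining_outputs(mining, file.path(dir, "out"))
  rings <- utils::read.delim(paths[["rings"]])
  expect_true(all(rings$color %in%
                    c("blue", "cyan", "magenta", "orange", "black")))
  # category map attaches labels
  map <- file.path(dir, "map.tsv")
  utils::write.table(
    data.frame(genome_id = genomes$genome_id[1], category = "ANME-2"),
    map, sep = "\t", quote = FALSE, row.names = FALSE)
  withmap <- read_genome_table(sim$paths[["genomes"]], map)
  expect_identical(withmap$category[1], "ANME-2")
  expect_identical(withmap$category[2], "unknown")
})
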