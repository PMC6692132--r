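test_that("classification agrees with exhaustive mutant-codon translation", {
  gc <- genetic_code_11()
  sense <- names(gc)[gc != "*"]
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (codon in sense) {
    cds <- toy_cds(codon)
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      for (alt in setdiff(bases, ref)) {
        mutant_codon <- codon
        substr(mutant_codon, pos, pos) <- alt
        expected <- if (gc[[mutant_codon]] == "*") "nonsense"
          else if (gc[[mutant_codon]] == gc[[codon]]) "synonymous"
          else "nonsynonymous"
        got <- classify_mutation(cds, point_mutation(3 + pos, ref, alt))
        expect_identical(got, expected)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, length(sense) * 9)
})

test_that("classification rejects coordinate and reference errors", {
  cds <- coding_sequence("ATGGGTAAAGGCTAA")
  expect_error(classify_mutation(cds, point_mutation(99, "A", "G")),
               "beyond CDS end")
  expect_error(classify_mutation(cds, point_mutation(5, "C", "A")),
               "reference mismatch")
  # substitutions in the stop codon are not sense-codon mutations
  expect_error(classify_mutation(cds, point_mutation(14, "A", "G")),
               "stop codon")
})

test_that("coding sequence invariants are enforced", {
  expect_error(coding_sequence("ATGGGTAA"), "divisible by 3")
  expect_error(coding_sequence("CCCGGTAAATAA"), "start codon")
  expect_error(coding_sequence("ATGGGTAAAGGC"), "end with a stop")
  expect_error(coding_sequence("ATGTAAAAATAA"), "internal in-frame stop")
  expect_silent(coding_sequence("GTGGGTAAAGGCTAA"))  # GTG start accepted
})

test_that("mutation labels follow gene notation", {
  cds <- coding_sequence("ATGGGTTGGGGCTAA")
  syn <- point_mutation(6, "T", "C")       # GGT -> GGC, codon 2
  expect_identical(mutation_label(cds, syn), "G2G")
  expect_identical(site_label(cds, syn), "2-3C")
  stopg <- point_mutation(9, "G", "A")     # TGG -> TGA, codon 3
  expect_identical(mutation_label(cds, stopg), "W3*")
})

test_that("CAI equals the geometric mean computed by an independent loop", {
  set.seed(42)
  gc <- genetic_code_11()
  sense <- names(gc)[gc != "*"]
  ref <- paste(sample(sense, 600, replace = TRUE), collapse = "")
  usage <- codon_usage_table(ref)
  gene_codons <- sample(sense, 100, replace = TRUE)
  res <- compute_cai(gene_codons, usage)
  # brute-force oracle: loop over codons, accumulate log weights
  single <- c("M", "W")
  acc <- c()
  for (cod in gene_codons) {
    if (gc[[cod]] %in% single || gc[[cod]] == "*") next
    acc <- c(acc, log(usage$weights[[cod]]))
  }
  expect_equal(res$cai, exp(mean(acc)), tolerance = 1e-12)
  expect_equal(res$n_included, length(acc))
  expect_true(res$cai > 0 && res$cai <= 1)
})

test_that("CAI is 1 for a gene of preferred codons and obeys swap algebra", {
  usage <- usage_from_seqs(paste(rep("GGTGGCAAAAAG", 20), collapse = ""),
                           "GGTAAA")
  best <- names(which(usage$weights == 1))
  gene <- rep(intersect(best, c("GGT", "GGC", "AAA", "AAG"))[1:2], 10)
  expect_equal(compute_cai(gene, usage)$cai, 1)

  # swapping one codon rescales CAI by (w_new / w_old)^(1/L)
  gene2 <- c(rep("GGT", 9), "GGC")
  L <- 10
  ratio <- compute_cai(gene2, usage)$cai / compute_cai(rep("GGT", 10), usage)$cai
  expect_equal(ratio,
               (usage$weights[["GGC"]] / usage$weights[["GGT"]])^(1 / L),
               tolerance = 1e-12)
})

test_that("codon usage weights are scale invariant with family maxima at 1", {
  ref <- "GGTGGTGGCAAAAAGTTT"
  u1 <- codon_usage_table(ref)
  u3 <- codon_usage_table(rep(ref, 3))  # triple every count
  # invariance holds for observed codons; unseen codons are pinned by the
  # 0.5-count smoothing and so shrink as the reference grows
  observed <- names(u1$counts)[u1$counts >= 1]
  expect_equal(u1$weights[observed], u3$weights[observed])
  gc <- genetic_code_11()
  fam_max <- tapply(u1$weights, gc[names(u1$weights)], max)
  expect_true(all(abs(fam_max - 1) < 1e-12))
})

test_that("tAI weights follow the wobble rules and scale invariance", {
  # one codon type decoded by its Watson-Crick tRNA only: tAI = 1
  trna1 <- trna_copy_table(data.frame(anticodon = "ACC", copies = 2),
                           penalties = c(sGU = 1, sIC = 1, sIA = 1, sUG = 1))
  expect_equal(compute_tai(rep("GGT", 5), trna1)$tai, 1)

  # doubling all copy numbers leaves tAI unchanged
  set.seed(3)
  gc <- genetic_code_11()
  sense <- names(gc)[gc != "*"]
  antis <- vapply(sample(sense, 25), function(cod)
    paste(rev(strsplit(chartr("ACGT", "TGCA", cod), "")[[1]]), collapse = ""),
    character(1))
  tab <- data.frame(anticodon = antis, copies = 1 + rpois(25, 2))
  gene <- sample(sense, 40, replace = TRUE)
  t1 <- compute_tai(gene, trna_copy_table(tab))
  tab2 <- tab; tab2$copies <- tab2$copies * 2
  t2 <- compute_tai(gene, trna_copy_table(tab2))
  expect_equal(t1$tai, t2$tai, tolerance = 1e-12)
})

test_that("tAI matches a hand-computed toy case", {
  # 3 tRNAs: GCC (reads GGC WC, GGT by G:U), TCC (reads GGA WC, GGG by U:G),
  # TTT (reads AAA WC, AAG by U:G)
  trna <- trna_copy_table(data.frame(anticodon = c("GCC", "TCC", "TTT"),
                                     copies = c(4, 2, 1)))
  p <- c(sGU = 0.41, sIC = 0.28, sIA = 0.9999, sUG = 0.68)
  W <- c(GGC = 4, GGT = (1 - p[["sGU"]]) * 4, GGA = 2,
         GGG = (1 - p[["sUG"]]) * 2, AAA = 1, AAG = (1 - p[["sUG"]]) * 1)
  gene <- c("GGC", "GGC", "GGT", "GGA", "GGG", "AAA", "AAG", "GGC", "GGT", "AAA")
  w_rel <- W / max(W)
  expect_equal(compute_tai(gene, trna)$tai,
               exp(mean(log(w_rel[gene]))), tolerance = 1e-12)
})

test_that("metric changes and ordering are permutation invariant", {
  set.seed(9)
  gc <- genetic_code_11()
  sense <- names(gc)[gc != "*"]
  ref <- paste(sample(sense, 400, replace = TRUE), collapse = "")
  usage <- codon_usage_table(ref)
  gene <- sample(sense, 60, replace = TRUE)
  perm <- sample(gene)
  expect_equal(compute_cai(gene, usage)$cai, compute_cai(perm, usage)$cai)
})

test_that("delta metrics recompute both CAIs and measure start distance", {
  usage <- usage_from_seqs("GGTGGTGGCAAAAAGTTTTTC")
  cds <- toy_cds(c("GGT", "AAA", "TTT"))
  mut <- point_mutation(6, "T", "C")  # GGT -> GGC synonymous
  d <- delta_metrics(cds, mut, usage)
  expect_equal(d$delta_cai,
               compute_cai(apply_mutation(cds, mut), usage)$cai -
                 compute_cai(cds, usage)$cai)
  expect_equal(d$codon_index, 2L)
  expect_equal(d$distance_from_start_nt, 5L)
  expect_identical(d$class, "synonymous")
  # a swap between equal-weight codons changes nothing
  u_eq <- usage_from_seqs("GGTGGCGGTGGC")
  expect_equal(delta_metrics(cds, mut, u_eq)$delta_cai, 0)
  # mutation at position 1 of codon 1 sits at distance 0
  cds1 <- coding_sequence("TTGGGTAAATAA")
  m1 <- point_mutation(1, "T", "G")  # TTG -> GTG start, Leu -> Val
  expect_equal(delta_metrics(cds1, m1, usage)$distance_from_start_nt, 0L)
  # nonsense rejected
  cds_w <- toy_cds("TGG")
  expect_error(delta_metrics(cds_w, point_mutation(6, "G", "A"), usage),
               "nonsense")
})

test_that("mRNA windows are centred with the stated convention", {
  set.seed(5)
  gc <- genetic_code_11()
  sense <- names(gc)[gc != "*"]
  cds <- toy_cds(sample(sense, 80, replace = TRUE))
  p <- 100
  ref <- substr(cds$nucleotides, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  w <- extract_mrna_window(cds, point_mutation(p, ref, alt), width = 42)
  expect_equal(w$start, 79)
  expect_equal(w$end, 120)
  expect_equal(nchar(w$ref_window), 42)
  expect_false(w$truncated)
  diff_at <- which(strsplit(w$ref_window, "")[[1]] !=
                     strsplit(w$mut_window, "")[[1]])
  expect_equal(diff_at - 1L, 21L)   # 0-based centre-right position
  expect_equal(w$mut_offset, 21L)

  # near the 5' end without flanks the window is left-truncated and flagged
  p5 <- 5
  ref5 <- substr(cds$nucleotides, p5, p5)
  alt5 <- setdiff(c("A", "C", "G", "T"), ref5)[1]
  w5 <- extract_mrna_window(cds, point_mutation(p5, ref5, alt5), width = 42)
  expect_true(w5$truncated)
  expect_equal(w5$start, 1)

  # with enough flanking sequence the same window is complete
  cds_fl <- coding_sequence(cds$nucleotides, flank5 = strrep("A", 30),
                            flank3 = strrep("A", 30))
  w5f <- extract_mrna_window(cds_fl, point_mutation(p5, ref5, alt5), width = 42)
  expect_false(w5f$truncated)
  expect_equal(nchar(w5f$ref_window), 42)
})

test_that("ramp test finds a planted early-gene rare-codon excess", {
  # usage with a clear preferred/rare split in the Gly family
  usage <- usage_from_seqs(paste(c(rep("GGT", 50), "GGC"), collapse = ""))
  planted <- toy_cds(c(rep("GGC", 50), rep("GGT", 60)))
  rp <- ramp_test(planted, usage, B = 499, seed = 1)
  expect_lt(rp$contrast$p_perm[["early"]], 0.01)
  expect_lt(rp$contrast$coefficients[["early"]], 0)

  # constant weights: no trend, p at the null
  flat <- toy_cds(rep("GGT", 110))
  rf <- ramp_test(flat, usage, B = 199, seed = 1)
  expect_equal(unname(rf$trend$f_obs["index"]), 0)
  expect_equal(unname(rf$trend$p_perm["index"]), 1)

  # strictly increasing weights: smallest attainable p
  inc <- permlm(weight ~ index,
                data.frame(index = 1:60, weight = seq(0.1, 1, length.out = 60)),
                B = 199, seed = 1)
  expect_equal(unname(inc$p_perm["index"]), 1 / 200)

  expect_warning(ramp_test(toy_cds(rep("GGT", 20)), usage, B = 99),
                 "contrast skipped")
})
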