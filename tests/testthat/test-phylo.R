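test_that("polytomy resolution preserves tips and resolves fully", {
  tree <- ape::read.tree(text = "((a,b),(c,(d,e,f,g)));")
  res <- resolve_polytomies(tree, n_resolutions = 25, seed = 1)
  expect_length(res, 25)
  for (tr in res) {
    expect_true(ape::is.binary(tr))
    expect_setequal(tr$tip.label, tree$tip.label)
  }
  # already-bifurcating input: every resolution is the same topology
  btree <- ape::read.tree(text = "((a,b),(c,d));")
  bres <- resolve_polytomies(btree, n_resolutions = 10, seed = 1)
  for (tr in bres)
    expect_true(ape::all.equal.phylo(tr, btree, use.edge.length = FALSE))
})

test_that("a 3-child polytomy is resolved into all 3 rooted shapes", {
  tree <- ape::read.tree(text = "(a,(b,c,d));")
  res <- resolve_polytomies(tree, n_resolutions = 120, seed = 2)
  sister_of <- vapply(res, function(tr) {
    # identify which pair of {b,c,d} forms a cherry
    pairs <- combn(c("b", "c", "d"), 2)
    for (j in 1:3) {
      mrca <- ape::getMRCA(tr, pairs[, j])
      kids <- tr$edge[tr$edge[, 1] == mrca, 2]
      if (all(kids <= ape::Ntip(tr)) &&
          setequal(tr$tip.label[kids], pairs[, j]))
        return(paste(pairs[, j], collapse = ""))
    }
    "none"
  }, character(1))
  expect_setequal(unique(sister_of), c("bc", "bd", "cd"))
})

test_that("Fitch pass scores trivial configurations correctly", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  zero <- fitch_ancestral(tree, c(a = 0, b = 0, c = 0, d = 0))
  expect_equal(zero$score, 0)
  internal <- (ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode)
  expect_true(all(zero$sets[internal, "0"]))
  expect_false(any(zero$sets[internal, "1"]))

  one <- fitch_ancestral(tree, c(a = 0, b = 0, c = 1, d = 1))
  expect_equal(one$score, 1)
  two <- fitch_ancestral(tree, c(a = 0, b = 1, c = 0, d = 1))
  expect_equal(two$score, 2)
  expect_error(fitch_ancestral(ape::read.tree(text = "(a,b,c,d);"),
                               c(a = 0, b = 0, c = 1, d = 1)), "bifurcating")
})

test_that("Fitch scores equal brute-force enumeration minima", {
  set.seed(33)
  for (i in 1:100) {
    inst <- random_parsimony_instance(sample(4:8, 1))
    expect_equal(fitch_ancestral(inst$tree, inst$states)$score,
                 brute_force_parsimony(inst$tree, inst$states))
  }
})

test_that("Fitch scores agree with phangorn on random instances", {
  skip_if_not_installed("phangorn")
  set.seed(34)
  for (i in 1:25) {
    inst <- random_parsimony_instance(sample(5:12, 1))
    pd <- phangorn::phyDat(matrix(as.character(inst$states),
                                  ncol = 1,
                                  dimnames = list(names(inst$states), NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(fitch_ancestral(inst$tree, inst$states)$score,
                 as.integer(phangorn::parsimony(inst$tree, pd,
                                                method = "fitch")))
  }
})

test_that("Fitch score is invariant to tip order and rerooting", {
  set.seed(35)
  inst <- random_parsimony_instance(8)
  s0 <- fitch_ancestral(inst$tree, inst$states)$score
  shuffled <- inst$states[sample(names(inst$states))]
  expect_equal(fitch_ancestral(inst$tree, shuffled)$score, s0)
  for (tip in inst$tree$tip.label[1:4]) {
    rerooted <- ape::root(ape::unroot(inst$tree), outgroup = tip,
                          resolve.root = TRUE)
    expect_equal(fitch_ancestral(rerooted, inst$states)$score, s0)
  }
})

test_that("event counting totals equal the parsimony score", {
  set.seed(36)
  for (i in 1:100) {
    inst <- random_parsimony_instance(sample(4:10, 1))
    sc <- fitch_ancestral(inst$tree, inst$states)$score
    acc <- count_events(inst$tree, inst$states, attribution = "acctran")
    del <- count_events(inst$tree, inst$states, attribution = "deltran")
    expect_equal(acc$total, sc)
    expect_equal(del$total, sc)
    expect_equal(sum(acc$edge_changes), acc$total)
  }
  # the single 0 -> 1 transition sits on exactly one branch
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  ce <- count_events(tree, c(a = 0, b = 0, c = 1, d = 1))
  expect_equal(sum(ce$edge_changes), 1)
  cd <- ape::getMRCA(tree, c("c", "d"))
  expect_true(ce$edge_changes[tree$edge[, 2] == cd])
})

test_that("site summaries separate clade-confined from scattered mutants", {
  tree <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  states <- rbind(
    absent    = setNames(rep(0L, 8), letters[1:8]),
    single    = setNames(c(1L, rep(0L, 7)), letters[1:8]),
    clade     = setNames(c(1L, 1L, 1L, 1L, rep(0L, 4)), letters[1:8]),
    scattered = setNames(c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L), letters[1:8]))
  ss <- suppressMessages(site_summary(tree, states, n_resolutions = 5, seed = 1))
  expect_equal(ss$events_mean[ss$site == "absent"], 0)
  expect_equal(ss$presence[ss$site == "absent"], 0L)
  expect_equal(ss$presence_tip[ss$site == "absent"], 0L)
  expect_equal(ss$events_min[ss$site == "single"], 1)
  expect_equal(ss$events_max[ss$site == "single"], 1)
  expect_equal(ss$presence[ss$site == "single"], 1L)
  expect_equal(ss$events_mean[ss$site == "clade"], 1)
  expect_equal(ss$events_mean[ss$site == "scattered"], 4)
  freq <- attr(ss, "node_state_frequency")
  expect_true(all(freq >= 0 & freq <= 1))
  expect_equal(unname(freq["absent", ]), rep(0, ncol(freq)))
})

test_that("ensemble means are seed-reproducible and stable across seeds", {
  tree <- ape::read.tree(text = "((a,b),(c,(d,e,f,(g,h,i))));")
  set.seed(37)
  states <- matrix(sample(0:1, 9 * 6, replace = TRUE), nrow = 6,
                   dimnames = list(paste0("s", 1:6), letters[1:9]))
  s1 <- site_summary(tree, states, n_resolutions = 100, seed = 5)
  s2 <- site_summary(tree, states, n_resolutions = 100, seed = 5)
  expect_identical(s1$events_mean, s2$events_mean)
  s3 <- site_summary(tree, states, n_resolutions = 100, seed = 6)
  expect_lt(max(abs(s1$events_mean - s3$events_mean)), 0.1)
})

test_that("presence model recovers a planted fitness effect", {
  cfg <- sim_config(seed = 71, n_syn = 100L, n_nonsyn = 100L, n_nonsense = 0L,
                    tree = list(n_tips = 40L))
  td <- simulate_true_dfe(cfg)
  ts <- simulate_tree_and_states(td, cfg)
  pres <- data.frame(mutation_id = rownames(ts$states),
                     presence = as.integer(rowSums(ts$states) > 0))
  ft <- data.frame(mutation_id = td$mutation_id, w_mean = td$true_w)
  pm <- presence_model(pres, ft, B = 199, seed = 1)
  expect_gt(pm$slope, 0)
  expect_lt(pm$p_lrt, 0.05)
  expect_lt(pm$p_perm, 0.05)

  # degenerate outcome rejected
  pres0 <- pres; pres0$presence <- 1L
  expect_error(presence_model(pres0, ft, B = 9), "degenerate")
  expect_error(presence_model(pres[1:5, ], ft, B = 9), "fewer than 10")
})

test_that("presence model keeps its nominal size under the null", {
  set.seed(38)
  rejections <- vapply(1:200, function(i) {
    d_pres <- data.frame(mutation_id = sprintf("m%02d", 1:40),
                         presence = rbinom(40, 1, 0.4))
    d_fit <- data.frame(mutation_id = sprintf("m%02d", 1:40),
                        w_mean = exp(rnorm(40, 0, 0.05)))
    pm <- tryCatch(presence_model(d_pres, d_fit, B = 99),
                   error = function(e) NULL)
    if (is.null(pm)) return(NA)
    pm$p_perm <= 0.05
  }, logical(1))
  rate <- mean(rejections, na.rm = TRUE)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.1)
})
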