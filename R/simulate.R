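#' Configuration of the synthetic-data generator
#'
#' Bundles every parameter of the simulated study: mutation counts per
#' class, the mixture defining the true DFE (a Generalised-Pareto
#' beneficial tail plus truncated-Gaussian near-neutral and deleterious
#' components on `s = w - 1`), the competition-assay sampling design
#' (replicates, colonies per plate, doublings), the linear
#' expression-fitness relation, and the phylogeny/tip-state model in which
#' the probability that a mutation is present on the tree increases with
#' log fitness. Defaults mirror the competition study the generator
#' emulates: 39 synonymous, 65 nonsynonymous and 6 nonsense mutations with
#' about 55/104 of non-nonsense mutations beneficial, a beneficial tail
#' with shape -0.35, four-to-six-replicate assays at about 6.7 doublings,
#' and a 77-tip phylogeny with polytomies.
#'
#' Identical configurations (including `seed`) produce byte-identical
#' output files; each simulation stage draws from its own seed substream
#' derived from the master seed.
#'
#' @param seed master RNG seed (integer).
#' @param n_syn,n_nonsyn,n_nonsense mutation counts per class.
#' @param dfe_mixture list: `p_beneficial`, `tail_tau`, `tail_kappa`,
#'   `deleterious_mean`, `deleterious_sd`, `neutral_sd`, `p_deleterious`
#'   (probability a non-beneficial draw is deleterious rather than
#'   near-neutral), `nonsense_shift` (added to the deleterious mean for
#'   nonsense mutations).
#' @param assay list: `n_replicates`, `colonies_sampled`, `doublings`.
#' @param expression list: `slope`, `intercept`, `noise_sd`,
#'   `n_synonymous` (how many synonymous mutants get expression data).
#' @param tree list: `n_tips`, `polytomy_fraction`,
#'   `presence_logit_slope`, `presence_logit_intercept`.
#' @param gene_length_codons total gene length in codons, start and stop
#'   included.
#' @return object of class `"sim_config"` (a validated nested list).
#' @export
sim_config <- function(seed = 1L,
                       n_syn = 39L, n_nonsyn = 65L, n_nonsense = 6L,
                       dfe_mixture = list(),
                       assay = list(),
                       expression = list(),
                       tree = list(),
                       gene_length_codons = 304L) {
  dfe_mixture <- utils::modifyList(list(
    p_beneficial = 55 / 104, tail_tau = 0.05, tail_kappa = -0.35,
    deleterious_mean = -0.1, deleterious_sd = 0.05, neutral_sd = 0.01,
    p_deleterious = 0.5, nonsense_shift = -0.6), dfe_mixture)
  assay <- utils::modifyList(list(
    n_replicates = 5L, colonies_sampled = 200L, doublings = 6.7), assay)
  expression <- utils::modifyList(list(
    slope = 10, intercept = -9, noise_sd = 0.27, n_synonymous = 27L),
    expression)
  tree <- utils::modifyList(list(
    n_tips = 77L, polytomy_fraction = 0.2,
    presence_logit_slope = 8, presence_logit_intercept = -1), tree)

  cfg <- list(seed = as.integer(seed),
              n_syn = as.integer(n_syn), n_nonsyn = as.integer(n_nonsyn),
              n_nonsense = as.integer(n_nonsense),
              dfe_mixture = dfe_mixture, assay = assay,
              expression = expression, tree = tree,
              gene_length_codons = as.integer(gene_length_codons))

  with(cfg, {
    stopifnot(n_syn >= 0, n_nonsyn >= 0, n_nonsense >= 0,
              gene_length_codons >= 4)
    stopifnot(dfe_mixture$p_beneficial >= 0, dfe_mixture$p_beneficial <= 1,
              dfe_mixture$p_deleterious >= 0, dfe_mixture$p_deleterious <= 1,
              dfe_mixture$deleterious_sd >= 0, dfe_mixture$neutral_sd >= 0)
    if (!is.finite(dfe_mixture$tail_tau) || dfe_mixture$tail_tau <= 0 ||
        !is.finite(dfe_mixture$tail_kappa))
      stop("invalid GPD tail: need finite tail_kappa and tail_tau > 0")
    stopifnot(assay$n_replicates >= 1, assay$colonies_sampled >= 1,
              assay$doublings > 0)
    stopifnot(expression$noise_sd >= 0)
    stopifnot(tree$n_tips >= 4, tree$polytomy_fraction >= 0,
              tree$polytomy_fraction <= 1)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config seed=%d: %d syn + %d nonsyn + %d nonsense; ",
              x$seed, x$n_syn, x$n_nonsyn, x$n_nonsense))
  cat(sprintf("tail GPD(tau=%.3g, kappa=%.3g), p_beneficial=%.3g>\n",
              x$dfe_mixture$tail_tau, x$dfe_mixture$tail_kappa,
              x$dfe_mixture$p_beneficial))
  invisible(x)
}

# per-stage seed substreams derived from the master seed
stage_seed <- function(config, stage) {
  stages <- c("gene", "dfe", "competitions", "expression", "tree", "trna",
              "reference")
  derive_seeds(config$seed, length(stages))[match(stage, stages)]
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  left <- seq_len(n)
  while (length(left) > 0) {
    z <- rnorm(length(left), mean, sd)
    ok <- z > lower & z <= upper
    out[left[ok]] <- z[ok]
    left <- left[!ok]
  }
  out
}

#' Simulate true fitness effects for a mutation set
#'
#' Draws each mutation's true relative fitness from the configured mixture:
#' synonymous and nonsynonymous mutations are beneficial with probability
#' `p_beneficial`, in which case `s = w - 1` is an exact GPD(tail_tau,
#' tail_kappa) draw; otherwise `s` comes from a half-Gaussian near-neutral
#' component or a truncated-Gaussian deleterious component, both confined
#' to `(-1, 0]`. Nonsense mutations are drawn from the deleterious
#' component shifted strongly negative by `nonsense_shift`. The mode of the
#' resulting DFE sits near neutrality (`w ~ 1`).
#'
#' @param config a [sim_config()].
#' @return data.frame with `mutation_id`, `class`, `true_w`.
#' @export
simulate_true_dfe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mx <- config$dfe_mixture
  n_sense <- config$n_syn + config$n_nonsyn
  with_seed(stage_seed(config, "dfe"), {
    draw_sense <- function(n) {
      s <- numeric(n)
      ben <- runif(n) < mx$p_beneficial
      s[ben] <- rgpd(sum(ben), mx$tail_tau, mx$tail_kappa)
      nb <- which(!ben)
      del <- runif(length(nb)) < mx$p_deleterious
      if (any(del))
        s[nb[del]] <- rnorm_trunc(sum(del), mx$deleterious_mean,
                                  mx$deleterious_sd, -1, 0)
      if (any(!del))
        s[nb[!del]] <- -abs(rnorm_trunc(sum(!del), 0, mx$neutral_sd, -1, 1))
      s
    }
    s_sense <- draw_sense(n_sense)
    s_nonsense <- if (config$n_nonsense > 0)
      rnorm_trunc(config$n_nonsense, mx$deleterious_mean + mx$nonsense_shift,
                  mx$deleterious_sd, -1, 0)
    else numeric(0)
    cls <- c(rep("synonymous", config$n_syn),
             rep("nonsynonymous", config$n_nonsyn),
             rep("nonsense", config$n_nonsense))
    n <- length(cls)
    data.frame(mutation_id = sprintf("m%03d", seq_len(n)),
               class = cls,
               true_w = 1 + c(s_sense, s_nonsense),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a gene and substitutions realising the mutation classes
#'
#' Generates a random valid CDS (start codon, sense codons, terminal stop)
#' and, for every row of the true-DFE table, samples a single-nucleotide
#' substitution whose translated effect matches the row's class, so the
#' mutation list and the sequence are mutually consistent. The start and
#' stop codons are left unmutated.
#'
#' @param config a [sim_config()].
#' @param true_dfe output of [simulate_true_dfe()].
#' @return list with `cds` (a [coding_sequence()]) and `mutations`
#'   (data.frame `mutation_id`, `cds_position`, `ref_base`, `alt_base`,
#'   `class`).
#' @export
simulate_gene_and_mutations <- function(config, true_dfe) {
  gc <- genetic_code_11()
  sense <- names(gc)[gc != "*"]
  with_seed(stage_seed(config, "gene"), {
    body <- sample(sense, config$gene_length_codons - 2L, replace = TRUE)
    cds <- coding_sequence(paste(c("ATG", body, "TAA"), collapse = ""),
                           id = "sim_gene")
    L <- nchar(cds$nucleotides)
    positions <- 4:(L - 3)  # spare the start and stop codons
    bases <- c("A", "C", "G", "T")
    draw_one <- function(target_class) {
      for (i in 1:10000) {
        p <- sample(positions, 1)
        ref <- substr(cds$nucleotides, p, p)
        alt <- sample(setdiff(bases, ref), 1)
        mut <- point_mutation(p, ref, alt)
        if (classify_mutation(cds, mut) == target_class)
          return(c(p, ref, alt))
      }
      stop("could not realise a ", target_class, " substitution")
    }
    drawn <- t(vapply(true_dfe$class, draw_one, character(3)))
    mutations <- data.frame(mutation_id = true_dfe$mutation_id,
                            cds_position = as.integer(drawn[, 1]),
                            ref_base = drawn[, 2], alt_base = drawn[, 3],
                            class = true_dfe$class, stringsAsFactors = FALSE)
    rownames(mutations) <- NULL
    list(cds = cds, mutations = mutations)
  })
}

#' Simulate competition-assay colony counts
#'
#' For each mutation and replicate, the competition starts at a 1:1
#' mixture; after `d` doublings the expected mutant frequency is
#' `f0 w^d / (f0 w^d + (1 - f0))` with `f0 = 0.5`. Plated colony counts
#' are binomial samples of the plate total at the initial and final
#' frequencies, so mutant and reference counts sum to the plate total on
#' every plate. The initial plate total is `colonies_sampled`; the final
#' plating depth is adapted to the expected outcome -- the total is scaled
#' so the rarer strain is still expected at about `colonies_sampled / 2`
#' colonies -- emulating the choice of plating dilution that keeps both
#' strains countable even for strongly deleterious mutants (for
#' near-neutral mutants the final total is `colonies_sampled` as well).
#' With `noise = FALSE` the expected (possibly fractional) counts are
#' returned instead, in which case [replicate_fitness()] inverts to the
#' true `w` exactly.
#'
#' @param true_dfe data.frame with `mutation_id` and `true_w` (`> 0`).
#' @param config a [sim_config()].
#' @param noise draw binomial plate samples (TRUE) or return expected
#'   counts (FALSE).
#' @return data.frame with `mutation_id`, `replicate`, `mutant_initial`,
#'   `ref_initial`, `mutant_final`, `ref_final`, `doublings`.
#' @export
simulate_competitions <- function(true_dfe, config, noise = TRUE) {
  stopifnot(all(true_dfe$true_w > 0))
  a <- config$assay
  n <- nrow(true_dfe)
  f0 <- 0.5
  grid <- expand.grid(replicate = seq_len(a$n_replicates),
                      row = seq_len(n))
  w <- true_dfe$true_w[grid$row]
  ff <- f0 * w^a$doublings / (f0 * w^a$doublings + (1 - f0))
  m <- nrow(grid)
  # dilution-adjusted final plating: expected minority count ~ colonies/2
  n_final <- pmax(a$colonies_sampled,
                  ceiling(a$colonies_sampled / (2 * pmin(ff, 1 - ff))))
  with_seed(stage_seed(config, "competitions"), {
    if (noise) {
      mi <- rbinom(m, a$colonies_sampled, f0)
      mf <- rbinom(m, n_final, ff)
    } else {
      mi <- rep(a$colonies_sampled * f0, m)
      mf <- n_final * ff
    }
    data.frame(mutation_id = true_dfe$mutation_id[grid$row],
               replicate = grid$replicate,
               mutant_initial = mi, ref_initial = a$colonies_sampled - mi,
               mutant_final = mf, ref_final = n_final - mf,
               doublings = a$doublings, stringsAsFactors = FALSE)
  })
}

#' Simulate relative reporter expression linked to fitness
#'
#' Relative transcript-reporter expression for a subset of synonymous
#' mutations, linear in true fitness with Gaussian noise:
#' `expression = intercept + slope * w + N(0, noise_sd)`. With
#' `noise_sd = 0` a downstream regression recovers the slope and intercept
#' exactly.
#'
#' @inheritParams simulate_competitions
#' @return data.frame with `mutation_id`, `relative_expression`.
#' @export
simulate_expression <- function(true_dfe, config) {
  e <- config$expression
  syn <- true_dfe[true_dfe$class == "synonymous", , drop = FALSE]
  if (nrow(syn) == 0) syn <- true_dfe
  with_seed(stage_seed(config, "expression"), {
    k <- min(e$n_synonymous, nrow(syn))
    pick <- syn[sort(sample.int(nrow(syn), k)), , drop = FALSE]
    data.frame(mutation_id = pick$mutation_id,
               relative_expression = e$intercept + e$slope * pick$true_w +
                 rnorm(k, 0, e$noise_sd),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a phylogeny with polytomies and per-mutation tip states
#'
#' Draws a random rooted tree, collapses a fraction of its internal edges
#' into polytomies, and generates each mutation's binary tip-state pattern
#' directly at the pattern level: the mutation is present on at least one
#' tip with probability `plogis(intercept + slope * log w)`, and present
#' mutations occupy a small random set of tips. No sequence evolution is
#' simulated -- the downstream analysis consumes only binary states.
#'
#' @inheritParams simulate_competitions
#' @return list with `tree` (a `phylo`) and `states` (site-by-tip 0/1
#'   matrix, rownames = mutation ids).
#' @export
simulate_tree_and_states <- function(true_dfe, config) {
  tr <- config$tree
  with_seed(stage_seed(config, "tree"), {
    tree <- ape::rtree(tr$n_tips, rooted = TRUE)
    tree$tip.label <- sprintf("strain%02d", seq_len(tr$n_tips))
    n_internal <- tree$Nnode
    k <- round(tr$polytomy_fraction * n_internal)
    if (k > 0) {
      internal_children <- which(tree$edge[, 2] > ape::Ntip(tree))
      k <- min(k, length(internal_children))
      collapse <- sample(internal_children, k)
      tree$edge.length[collapse] <- 0
      tree <- ape::di2multi(tree, tol = 1e-12)
    }
    p_any <- stats::plogis(tr$presence_logit_intercept +
                             tr$presence_logit_slope * log(true_dfe$true_w))
    present <- runif(nrow(true_dfe)) < p_any
    states <- matrix(0L, nrow(true_dfe), tr$n_tips,
                     dimnames = list(true_dfe$mutation_id, tree$tip.label))
    for (i in which(present)) {
      k_tips <- 1 + rbinom(1, 3, 0.3)
      states[i, sample.int(tr$n_tips, k_tips)] <- 1L
    }
    list(tree = tree, states = states)
  })
}

#' Write a full synthetic data set to disk
#'
#' Runs every generator stage and writes the files the pipeline consumes:
#' `gene.fasta`, `mutations.csv`, `competitions.csv`,
#' `marker_control.csv` (reference-vs-wild-type competitions at true
#' `w = 1`), `expression.csv`, `tree.nwk`, `tip_states.csv`,
#' `trna_copies.csv` (random copy numbers over all Watson-Crick
#' anticodons), and `truth.json` holding the full configuration and the
#' true fitness table. Output is byte-identical across runs with the same
#' configuration.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list of the generated objects.
#' @export
write_simulated_data <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  true_dfe <- simulate_true_dfe(config)
  gm <- simulate_gene_and_mutations(config, true_dfe)
  comps <- simulate_competitions(true_dfe, config)
  ctrl_truth <- data.frame(mutation_id = "marker_control", class = "control",
                           true_w = 1, stringsAsFactors = FALSE)
  ctrl <- simulate_competitions(ctrl_truth, config)
  expr <- simulate_expression(true_dfe, config)
  ts <- simulate_tree_and_states(true_dfe, config)

  gc <- genetic_code_11()
  sense <- names(gc)[gc != "*"]
  trna <- with_seed(stage_seed(config, "trna"), {
    data.frame(anticodon = revcomp(sense),
               copies = 1 + rpois(length(sense), 2),
               stringsAsFactors = FALSE)
  })

  # reference gene set for CAI: genes with skewed codon usage, emulating a
  # highly expressed (e.g. ribosomal-protein) reference panel
  ref_genes <- with_seed(stage_seed(config, "reference"), {
    aa_fam <- split(sense, gc[sense])
    pref <- lapply(aa_fam, function(f) {
      p <- rexp(length(f))^2
      p / sum(p)
    })
    vapply(1:10, function(i) {
      aas <- sample(names(aa_fam), 200, replace = TRUE)
      cods <- vapply(aas, function(a)
        sample(aa_fam[[a]], 1, prob = pref[[a]]), character(1))
      paste(cods, collapse = "")
    }, character(1))
  })

  fa <- Biostrings::DNAStringSet(setNames(gm$cds$nucleotides, gm$cds$id))
  Biostrings::writeXStringSet(fa, file.path(dir, "gene.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(ref_genes, sprintf("ref%02d", 1:10))),
    file.path(dir, "reference_genes.fasta"))
  wr <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(gm$mutations, "mutations.csv")
  wr(comps, "competitions.csv")
  wr(ctrl, "marker_control.csv")
  wr(expr, "expression.csv")
  ape::write.tree(ts$tree, file.path(dir, "tree.nwk"))
  states_long <- data.frame(
    site = rep(rownames(ts$states), ncol(ts$states)),
    tip = rep(colnames(ts$states), each = nrow(ts$states)),
    state = as.integer(ts$states), stringsAsFactors = FALSE)
  wr(states_long[order(states_long$site, states_long$tip), ], "tip_states.csv")
  wr(trna, "trna_copies.csv")
  jsonlite::write_json(list(config = unclass(config), true_dfe = true_dfe),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(true_dfe = true_dfe, cds = gm$cds,
                 mutations = gm$mutations, competitions = comps,
                 marker_control = ctrl, expression = expr,
                 tree = ts$tree, states = ts$states, trna = trna,
                 reference_genes = ref_genes))
}
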