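#' Randomly resolve polytomies into an ensemble of bifurcating trees
#'
#' Draws `n_resolutions` independent bifurcating trees from a rooted tree
#' that may contain polytomies. Each polytomy is resolved by sequential
#' random pairing of its children (via [ape::multi2di()] with
#' `random = TRUE`); topology outside the polytomies is untouched and the
#' tip set is preserved. Deterministic under `seed`.
#'
#' @param tree an [ape::phylo] object (rooted; branch lengths, if any, are
#'   irrelevant to parsimony and carried through unchanged).
#' @param n_resolutions number of resolved trees to draw.
#' @param seed RNG seed (NULL = current stream).
#' @return list of strictly bifurcating `phylo` objects.
#' @export
resolve_polytomies <- function(tree, n_resolutions = 100, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_resolutions >= 1)
  if (!ape::is.rooted(tree)) {
    tree <- root_at_internal(tree)
    message("unrooted input tree rooted at an internal node for parsimony")
  }
  with_seed(seed, lapply(seq_len(n_resolutions), function(i)
    ape::multi2di(tree, random = TRUE)))
}

root_at_internal <- function(tree) {
  # root an unrooted tree along the first edge below a bifurcating internal
  # node; parsimony scores are unaffected by root placement
  ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
}

# children of each node, from the edge table
node_children <- function(tree) {
  kids <- vector("list", ape::Ntip(tree) + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

# internal nodes in postorder (parents after children)
postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1])
}

tip_state_sets <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  sets <- matrix(FALSE, ntip + tree$Nnode, 2,
                 dimnames = list(NULL, c("0", "1")))
  st <- states[tree$tip.label]
  n_missing <- sum(is.na(st))
  if (n_missing > 0)
    message(n_missing, " tip(s) without a state treated as ambiguous {0,1}")
  for (i in seq_len(ntip)) {
    if (is.na(st[i])) sets[i, ] <- TRUE
    else sets[i, st[i] + 1L] <- TRUE
  }
  sets
}

#' Fitch parsimony for a binary character on a bifurcating tree
#'
#' Bottom-up Fitch pass with the union/intersection rule: each internal
#' node receives the intersection of its children's state sets, or their
#' union when the intersection is empty, in which case one change is
#' scored. Tips missing from `states` are treated as ambiguous `{0,1}`
#' (reported). The score is the minimum number of state changes on the
#' tree; ancestral state sets are the per-node Fitch sets.
#'
#' @param tree rooted, strictly bifurcating `phylo`.
#' @param states named integer vector of tip states in `{0, 1}` (names =
#'   tip labels; 0 = ancestral, 1 = mutant).
#' @return list with `score` and `sets` (logical matrix, rows = nodes in
#'   ape numbering, columns = states "0"/"1").
#' @export
fitch_ancestral <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree))
    stop("tree must be strictly bifurcating; resolve polytomies first")
  sets <- tip_state_sets(tree, states)
  kids <- node_children(tree)
  score <- 0L
  for (v in postorder_nodes(tree)) {
    ch <- kids[[v]]
    inter <- sets[ch[1], ] & sets[ch[2], ]
    if (any(inter)) {
      sets[v, ] <- inter
    } else {
      sets[v, ] <- sets[ch[1], ] | sets[ch[2], ]
      score <- score + 1L
    }
  }
  list(score = score, sets = sets)
}

#' Count state transitions along branches of one reconstruction
#'
#' Resolves a single most-parsimonious reconstruction by dynamic
#' programming over unit change costs and counts a transition on every
#' branch whose parent and child states differ; the total always equals the
#' Fitch parsimony score. Where the reconstruction is ambiguous the
#' `attribution` rule breaks ties: `"acctran"` accelerates changes
#' (placing them on the earliest, root-most feasible branch), `"deltran"`
#' delays them tip-wards; totals are identical, only branch placement
#' differs. At a root tie the ancestral state 0 is preferred.
#'
#' @inheritParams fitch_ancestral
#' @param attribution `"acctran"` or `"deltran"`.
#' @return list with `total`, `node_states` (resolved state per node),
#'   `edge_changes` (logical per row of `tree$edge`).
#' @export
count_events <- function(tree, states, attribution = c("acctran", "deltran")) {
  attribution <- match.arg(attribution)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree))
    stop("tree must be strictly bifurcating; resolve polytomies first")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kids <- node_children(tree)
  st <- states[tree$tip.label]

  # Sankoff costs: cost[v, s+1] = min changes in the subtree of v given
  # state s at v
  cost <- matrix(Inf, nn, 2)
  for (i in seq_len(ntip)) {
    if (is.na(st[i])) cost[i, ] <- 0
    else cost[i, st[i] + 1L] <- 0
  }
  po <- postorder_nodes(tree)
  for (v in po) {
    for (s in 0:1) {
      tot <- 0
      for (c_ in kids[[v]])
        tot <- tot + min(cost[c_, s + 1L], cost[c_, 2L - s] + 1)
      cost[v, s + 1L] <- tot
    }
  }
  root <- po[length(po)]
  node_states <- integer(nn)
  root_s <- if (cost[root, 1] <= cost[root, 2]) 0L else 1L
  node_states[root] <- root_s

  # preorder assignment with the tie-break rule
  for (v in rev(po)) {
    sp <- node_states[v]
    for (c_ in kids[[v]]) {
      stay <- cost[c_, sp + 1L]
      move <- cost[c_, 2L - sp] + 1
      if (stay < move) {
        node_states[c_] <- sp
      } else if (move < stay) {
        node_states[c_] <- 1L - sp
      } else {
        node_states[c_] <- if (attribution == "acctran") 1L - sp else sp
      }
    }
  }
  edge_changes <- node_states[tree$edge[, 1]] != node_states[tree$edge[, 2]]
  list(total = sum(edge_changes), node_states = node_states,
       edge_changes = edge_changes)
}

# key identifying an internal node by its clade's tip-label set
clade_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kids <- node_children(tree)
  tipsets <- vector("list", nn)
  for (i in seq_len(ntip)) tipsets[[i]] <- tree$tip.label[i]
  po <- postorder_nodes(tree)
  for (v in po)
    tipsets[[v]] <- sort(unique(unlist(tipsets[kids[[v]]])))
  keys <- vapply(po, function(v) paste(tipsets[[v]], collapse = "|"),
                 character(1))
  setNames(po, keys)
}

as_state_matrix <- function(states) {
  if (is.matrix(states)) return(states)
  if (is.data.frame(states) && all(c("site", "tip", "state") %in% names(states))) {
    sites <- unique(states$site)
    tips <- unique(states$tip)
    m <- matrix(NA_integer_, length(sites), length(tips),
                dimnames = list(sites, tips))
    m[cbind(match(states$site, sites), match(states$tip, tips))] <-
      as.integer(states$state)
    return(m)
  }
  stop("tip states must be a site-by-tip matrix or a long data.frame ",
       "with columns site, tip, state")
}

#' Per-site presence and independent-origin summary over a tree ensemble
#'
#' For each mutation site, runs Fitch parsimony and transition counting on
#' every randomly resolved bifurcation of the input tree and aggregates the
#' number of inferred evolutionary events (independent origins of the
#' mutant state). Two presence indicators are emitted: `presence_tip`, the
#' raw occurrence of the mutant state on at least one tip, and `presence`,
#' which additionally requires a mean inferred origin count of at least one
#' across the ensemble, so that shared ancestry alone does not count a
#' mutation as repeatedly observed. Mean frequency of the inferred mutant
#' state at each internal node of the input tree (matched across
#' resolutions by clade) is returned as an attribute.
#'
#' @param tree rooted `phylo`, polytomies allowed.
#' @param states site-by-tip 0/1 matrix (rownames = site ids) or long
#'   data.frame with columns `site`, `tip`, `state`.
#' @param n_resolutions number of random resolutions.
#' @param seed RNG seed.
#' @param attribution passed to [count_events()].
#' @return data.frame (class `"site_event_summary"`) with one row per
#'   site: `site`, `n_tips_mutant`, `events_mean`, `events_min`,
#'   `events_max`, `presence_tip`, `presence`; attribute
#'   `node_state_frequency` is a site-by-node matrix of mutant-state
#'   frequencies at the input tree's internal nodes.
#' @export
site_summary <- function(tree, states, n_resolutions = 100, seed = NULL,
                         attribution = "acctran") {
  m <- as_state_matrix(states)
  missing_tips <- setdiff(tree$tip.label, colnames(m))
  if (length(missing_tips) > 0)
    message(length(missing_tips), " tip(s) absent from the state matrix ",
            "treated as ambiguous")
  trees <- resolve_polytomies(tree, n_resolutions, seed)
  orig_keys <- clade_keys(if (ape::is.rooted(tree)) tree else root_at_internal(tree))
  res_keys <- lapply(trees, clade_keys)

  sites <- rownames(m)
  ev <- matrix(NA_real_, length(sites), n_resolutions)
  freq1 <- matrix(0, length(sites), length(orig_keys),
                  dimnames = list(sites, names(orig_keys)))
  for (r in seq_len(n_resolutions)) {
    tr <- trees[[r]]
    node_map <- res_keys[[r]][names(orig_keys)]  # original clade -> node id
    for (i in seq_along(sites)) {
      st <- setNames(m[i, ], colnames(m))
      ce <- count_events(tr, st, attribution = attribution)
      ev[i, r] <- ce$total
      freq1[i, ] <- freq1[i, ] + (ce$node_states[node_map] == 1L)
    }
  }
  freq1 <- freq1 / n_resolutions

  occ <- apply(m, 1, function(z) sum(z == 1, na.rm = TRUE))
  out <- data.frame(site = sites,
                    n_tips_mutant = as.integer(occ),
                    events_mean = rowMeans(ev),
                    events_min = apply(ev, 1, min),
                    events_max = apply(ev, 1, max),
                    stringsAsFactors = FALSE)
  out$presence_tip <- as.integer(out$n_tips_mutant >= 1)
  out$presence <- as.integer(out$presence_tip == 1 & out$events_mean >= 1)
  attr(out, "node_state_frequency") <- freq1
  attr(out, "n_resolutions") <- n_resolutions
  class(out) <- c("site_event_summary", "data.frame")
  out
}

#' @export
print.site_event_summary <- function(x, ...) {
  cat("Site event summary over", attr(x, "n_resolutions"),
      "tree resolutions:", nrow(x), "sites,",
      sum(x$presence), "present under the origin rule\n")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Binary model of phylogenetic presence on relative fitness
#'
#' Logistic regression of a mutation's presence/absence across the
#' phylogeny on its relative fitness, on the log-fitness scale by default
#' (`presence ~ log w`; a linear-in-w variant is available). Reports the
#' slope, the likelihood-ratio p-value against the intercept-only model,
#' and a label-permutation p-value (add-one convention). Complete
#' separation is detected from diverging coefficients and flagged; the
#' reported fit is then the penalised-by-truncation glm output and should
#' be read qualitatively.
#'
#' @param presence data.frame with `mutation_id` (or `site`) and a binary
#'   `presence` column, e.g. from [site_summary()].
#' @param fitness data.frame with `mutation_id` and `w_mean` (or `w`).
#' @param link `"log_w"` or `"linear_w"`.
#' @param B permutations for the permutation p-value.
#' @param seed RNG seed.
#' @return object of class `"presence_fit"`: `slope`, `p_lrt`, `p_perm`,
#'   `fit` (the `glm`), `link`, `n`, `separation`.
#' @export
presence_model <- function(presence, fitness, link = c("log_w", "linear_w"),
                           B = 1000, seed = NULL) {
  link <- match.arg(link)
  if (!"mutation_id" %in% names(presence) && "site" %in% names(presence))
    names(presence)[names(presence) == "site"] <- "mutation_id"
  wcol <- if ("w_mean" %in% names(fitness)) "w_mean" else "w"
  d <- merge(presence[, c("mutation_id", "presence")],
             fitness[, c("mutation_id", wcol)], by = "mutation_id")
  d <- d[complete.cases(d), ]
  if (nrow(d) < 10) stop("fewer than 10 joined mutations")
  if (length(unique(d$presence)) < 2)
    stop("degenerate outcome: presence constant across mutations")
  d$xv <- if (link == "log_w") log(d[[wcol]]) else d[[wcol]]

  fit1 <- suppressWarnings(glm(presence ~ xv, data = d, family = binomial()))
  fit0 <- glm(presence ~ 1, data = d, family = binomial())
  dev_obs <- fit0$deviance - fit1$deviance
  p_lrt <- pchisq(dev_obs, df = 1, lower.tail = FALSE)
  separation <- !fit1$converged || abs(coef(fit1)[2]) > 50 ||
    any(fitted(fit1) > 1 - 1e-8) && any(fitted(fit1) < 1e-8) &&
    dev_obs >= fit0$deviance - 1e-6
  if (separation)
    warning("possible complete separation in the presence model; ",
            "slope magnitude unreliable")

  dev_star <- with_seed(seed, vapply(seq_len(B), function(i) {
    di <- d
    di$presence <- sample(di$presence)
    f1 <- suppressWarnings(glm(presence ~ xv, data = di, family = binomial()))
    fit0$deviance - f1$deviance
  }, numeric(1)))
  p_perm <- (1 + sum(dev_star >= dev_obs - 1e-12)) / (B + 1)

  structure(list(slope = unname(coef(fit1)[2]), p_lrt = p_lrt,
                 p_perm = p_perm, fit = fit1, link = link,
                 n = nrow(d), separation = separation, B = B),
            class = "presence_fit")
}

#' @export
print.presence_fit <- function(x, ...) {
  cat(sprintf("Presence ~ %s logistic model (n = %d)\n",
              if (x$link == "log_w") "log(w)" else "w", x$n))
  cat(sprintf("  slope = %.4g;  LRT p = %.4g;  permutation p = %.4g (B = %d)\n",
              x$slope, x$p_lrt, x$p_perm, x$B))
  if (x$separation) cat("  WARNING: possible complete separation\n")
  invisible(x)
}
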