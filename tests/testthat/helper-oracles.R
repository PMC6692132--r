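# Independent oracles used across tests.

# Minimum number of binary state changes on a rooted bifurcating tree, by
# exhaustive enumeration of all internal-node labelings.
brute_force_parsimony <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  st <- states[tree$tip.label]
  internals <- (ntip + 1):nn
  best <- Inf
  for (mask in 0:(2^length(internals) - 1)) {
    lab <- integer(nn)
    lab[seq_len(ntip)] <- st
    lab[internals] <- as.integer(intToBits(mask))[seq_along(internals)]
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# random rooted bifurcating tree plus random binary tip states
random_parsimony_instance <- function(n_tips) {
  tree <- ape::rtree(n_tips, rooted = TRUE)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  states <- setNames(sample(0:1, n_tips, replace = TRUE), tree$tip.label)
  list(tree = tree, states = states)
}

# toy CDS: ATG + given codons + TAA
toy_cds <- function(codons, ...) {
  coding_sequence(paste(c("ATG", codons, "TAA"), collapse = ""), ...)
}

# usage table built from explicit codon count sequences
usage_from_seqs <- function(...) codon_usage_table(c(...))
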