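# Shared fixtures, built in code at test time.

links_df <- function(a, pa, b, pb, ...) {
  data.frame(protein_a = a, pos_a = pa, protein_b = b, pos_b = pb, ...,
             stringsAsFactors = FALSE)
}

# hand-placed two-chain model with exactly known coordinates
grid_model <- function() {
  chain <- function(xs) data.frame(
    auth_number = seq_along(xs), aa = rep("K", length(xs)),
    x = xs, y = 0, z = 0, present = TRUE, stringsAsFactors = FALSE)
  structure_model(list(A = chain(c(0, 10, 20, 60)),
                       B = chain(c(100, 110, 120, 160))), "grid")
}

# identity chain maps for a model whose chains ARE the full sequences
identity_maps <- function(model, accessions = NULL) {
  chains <- names(model$chains)
  if (is.null(accessions)) accessions <- paste0("P_", chains)
  lapply(seq_along(chains), function(i) {
    ch <- model$chains[[chains[i]]]
    structure(list(accession = accessions[i], chain_id = chains[i],
                   structure_id = model$structure_id,
                   mapping = setNames(seq_len(nrow(ch)),
                                      as.character(seq_len(nrow(ch)))),
                   identity = 1),
              class = "chain_map")
  })
}

# adjusted Rand index between two labelings (independent of the package)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# one shared mid-size toy complex per test run (expensive to rebuild)
toy_cache <- new.env()
get_toy <- function() {
  if (is.null(toy_cache$toy)) toy_cache$toy <- make_toy_complex(8, 100, seed = 101)
  toy_cache$toy
}

# independent modularity oracle: adjacency-matrix form of Q
modularity_oracle <- function(g, memb) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  memb <- memb[rownames(A)]
  k <- rowSums(A)
  m2 <- sum(k)
  same <- outer(memb, memb, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

# exhaustive one-sided (greater) hypergeometric tail via choose(), an
# oracle independent of fisher.test / dhyper
hyper_tail_greater <- function(a, b, cc, d) {
  m <- a + b; n2 <- cc + d; kk <- a + cc
  xs <- max(0, kk - n2):min(kk, m)
  probs <- choose(m, xs) * choose(n2, kk - xs) / choose(m + n2, kk)
  sum(probs[xs >= a])
}

# two-sided Fisher p by exhaustive enumeration of table probabilities
hyper_two_sided <- function(a, b, cc, d) {
  m <- a + b; n2 <- cc + d; kk <- a + cc
  xs <- max(0, kk - n2):min(kk, m)
  probs <- choose(m, xs) * choose(n2, kk - xs) / choose(m + n2, kk)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
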