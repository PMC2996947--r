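## Independent brute-force oracles used to check the package's statistics and
## signed path search. These deliberately share no code with the implementation.

## Exhaustive enumeration of all directed simple paths of <= depth edges from
## the root, recording every attainable path-sign product per terminal node.
oracle_polarity <- function(kam, root_entity, root_aspect, depth) {
  e <- kam$edges
  k <- function(en, a) paste(en, a, sep = "|")
  ek_s <- k(e$source_entity, e$source_aspect)
  ek_t <- k(e$target_entity, e$target_aspect)
  res <- list()
  grow <- function(path, sgn) {
    if (length(path) > depth) return(invisible())
    for (r in which(ek_s == path[length(path)])) {
      t <- ek_t[r]
      if (t %in% path) next
      s2 <- sgn * e$sign[r]
      res[[t]] <<- union(res[[t]], s2)
      grow(c(path, t), s2)
    }
  }
  grow(k(root_entity, root_aspect), 1L)
  res
}

## Hypothesis counts derived from the oracle polarity sets by definition.
oracle_hyp_counts <- function(kam, root_entity, root_aspect, universe_keys,
                              changed_dir, depth) {
  pol <- oracle_polarity(kam, root_entity, root_aspect, depth)
  pol <- pol[names(pol) %in% universe_keys]
  amb <- names(pol)[vapply(pol, length, integer(1)) == 2L]
  up <- names(pol)[vapply(pol, function(s) setequal(s, 1), logical(1))]
  dn <- names(pol)[vapply(pol, function(s) setequal(s, -1), logical(1))]
  P <- length(pol)
  chg <- names(changed_dir)
  Q <- length(intersect(names(pol), chg))
  K <- sum(changed_dir[intersect(up, chg)] == "increase") +
    sum(changed_dir[intersect(dn, chg)] == "decrease")
  J <- sum(changed_dir[intersect(up, chg)] == "decrease") +
    sum(changed_dir[intersect(dn, chg)] == "increase")
  list(N = length(universe_keys), M = length(changed_dir), P = P, Q = Q,
       J = J, K = K, ambiguous = sort(amb))
}

## Hypergeometric upper tail by direct summation over the support.
oracle_hyper_tail <- function(Q, N, M, P) {
  hi <- min(M, P)
  if (Q > hi) return(0)
  xs <- Q:hi
  sum(choose(M, xs) * choose(N - M, P - xs)) / choose(N, P)
}

## Binomial upper tail at null 0.5 by direct summation.
oracle_binom_tail <- function(J, K) {
  n <- J + K
  if (n == 0) return(1)
  H <- max(J, K)
  xs <- H:n
  sum(choose(n, xs)) * 0.5^n
}

## Step-up FDR adjustment written out longhand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

## Small random signed graph, cycles and contradictory edge pairs allowed.
helper_random_kam <- function(n_nodes, n_edges, seed, leaf_fraction = 0.5) {
  set.seed(seed)
  aspects <- ifelse(seq_len(n_nodes) <= ceiling(n_nodes * (1 - leaf_fraction)),
                    "protein_activity", "rna_abundance")
  ents <- sprintf("N%02d", seq_len(n_nodes))
  src <- sample.int(n_nodes, n_edges, replace = TRUE)
  tgt <- sample.int(n_nodes, n_edges, replace = TRUE)
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  edges <- data.frame(source_entity = ents[src], source_aspect = aspects[src],
                      sign = sample(c(-1L, 1L), sum(keep), replace = TRUE),
                      target_entity = ents[tgt], target_aspect = aspects[tgt],
                      stringsAsFactors = FALSE)
  kam(data.frame(entity = ents, aspect = aspects, stringsAsFactors = FALSE),
      edges, name = sprintf("rand%d", seed))
}

## Convenience: tiny kam from a compact edge spec "A.act +> B.rna".
helper_kam <- function(...) {
  specs <- c(...)
  short <- c(act = "protein_activity", rna = "rna_abundance",
             abd = "protein_abundance", mod = "protein_modification",
             cpd = "compound", prc = "process")
  parse_node <- function(s) {
    p <- strsplit(s, ".", fixed = TRUE)[[1]]
    c(p[1], short[[p[2]]])
  }
  rows <- lapply(specs, function(s) {
    f <- strsplit(s, " ", fixed = TRUE)[[1]]
    s1 <- parse_node(f[1]); s2 <- parse_node(f[3])
    data.frame(source_entity = s1[1], source_aspect = s1[2],
               sign = if (f[2] == "+>") 1L else -1L,
               target_entity = s2[1], target_aspect = s2[2],
               stringsAsFactors = FALSE)
  })
  e <- do.call(rbind, rows)
  n <- unique(data.frame(entity = c(e$source_entity, e$target_entity),
                         aspect = c(e$source_aspect, e$target_aspect),
                         stringsAsFactors = FALSE))
  kam(n, e)
}

## State-change set from compact "B.rna:increase" specs, plus no_change rows
## for the rest of a universe.
helper_changes <- function(...) {
  specs <- c(...)
  if (!length(specs)) {
    out <- data.frame(entity = character(), aspect = character(),
                      direction = character(), fold_change = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("state_change_set", "data.frame")
    return(out)
  }
  short <- c(act = "protein_activity", rna = "rna_abundance",
             abd = "protein_abundance", mod = "protein_modification",
             cpd = "compound", prc = "process")
  rows <- lapply(specs, function(s) {
    f <- strsplit(s, ":", fixed = TRUE)[[1]]
    p <- strsplit(f[1], ".", fixed = TRUE)[[1]]
    data.frame(entity = p[1], aspect = short[[p[2]]], direction = f[2],
               fold_change = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("state_change_set", "data.frame")
  out
}

helper_universe <- function(kam, exclude_entity = NULL) {
  u <- kam$nodes
  if (!is.null(exclude_entity)) u <- u[!u$entity %in% exclude_entity, , drop = FALSE]
  u
}
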