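# Independent oracles used across the test files. Each is a deliberately
# naive implementation (brute force / closed form) that never shares code with
# the package path it checks.

# --- brute-force labeled-graph isomorphism ------------------------------------
# g: list(labels = character, edges = data.frame(a, b, label))
iso_oracle <- function(g1, g2) {
  n <- length(g1$labels)
  if (n != length(g2$labels)) return(FALSE)
  if (nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  edge_key <- function(e, perm = seq_len(n)) {
    a <- perm[e$a]; b <- perm[e$b]
    sort(paste(pmin(a, b), pmax(a, b), e$label))
  }
  target <- edge_key(g2$edges)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(n))) {
    if (!all(g1$labels == g2$labels[p])) next
    # p maps g1 vertex i -> g2 vertex p[i]
    if (identical(edge_key(g1$edges, p), target)) return(TRUE)
  }
  FALSE
}

random_labeled_graph <- function(n, n_labels = 2, p_edge = 0.5) {
  labels <- sample(LETTERS[seq_len(n_labels)], n, replace = TRUE)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                      label = sample(c("s", "d"), sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  list(labels = labels, edges = edges)
}

permute_graph <- function(g, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  list(labels = g$labels[inv],
       edges = data.frame(a = perm[g$edges$a], b = perm[g$edges$b],
                          label = g$edges$label, stringsAsFactors = FALSE))
}

graph_string <- function(g) {
  reactAD:::canonical_graph_string(g$labels, g$edges$a, g$edges$b, g$edges$label)
}

# --- brute-force simple-path counting on a CGR --------------------------------
# counts all unordered simple paths with `sizes` atoms, by naive DFS over an
# adjacency list built directly from the cgr bond table
path_count_oracle <- function(cgr, sizes = 2:4) {
  maps <- cgr$atoms$map
  adj <- lapply(maps, function(m)
    c(cgr$bonds$a2[cgr$bonds$a1 == m], cgr$bonds$a1[cgr$bonds$a2 == m]))
  names(adj) <- as.character(maps)
  total <- 0L
  extend <- function(path) {
    if (length(path) %in% sizes && path[1] < path[length(path)])
      total <<- total + 1L
    if (length(path) >= max(sizes)) return(invisible(NULL))
    for (v in adj[[as.character(path[length(path)])]])
      if (!(v %in% path)) extend(c(path, v))
    invisible(NULL)
  }
  for (m in maps) extend(m)
  total
}

# --- pairwise AUC oracle ------------------------------------------------------
auc_pairwise_oracle <- function(abs_errors, decisions) {
  e_in <- abs_errors[decisions]; e_out <- abs_errors[!decisions]
  s <- 0
  for (a in e_in) for (b in e_out)
    s <- s + (b > a) + 0.5 * (b == a)
  s / (length(e_in) * length(e_out))
}

# --- closed-form RBF Gaussian process -----------------------------------------
gpr_oracle <- function(x, y, xt, alpha, gamma) {
  d2 <- function(a, b) outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  yc <- mean(y); ys <- sqrt(mean((y - yc)^2))
  k <- exp(-gamma * d2(x, x))
  ks <- exp(-gamma * d2(xt, x))
  ainv <- solve(k + alpha * diag(nrow(x)))
  list(mean = unname(as.numeric(ks %*% ainv %*% ((y - yc) / ys)) * ys + yc),
       var = unname(1 - rowSums((ks %*% ainv) * ks)))
}

# --- reaction atom-map relabelling --------------------------------------------
# relabels the atom-map numbers of a reaction SMILES by a random bijection;
# the result encodes the same reaction with a different atom ordering/naming
shuffle_maps <- function(smiles) {
  maps <- as.integer(unlist(regmatches(smiles, gregexpr("(?<=:)[0-9]+(?=\\])",
                                                        smiles, perl = TRUE))))
  u <- sort(unique(maps))
  new <- sample(u)
  out <- smiles
  # two-phase rewrite through a temporary token to avoid chained replacement
  for (i in seq_along(u))
    out <- gsub(paste0(":", u[i], "]"), paste0(":T", i, "]"), out, fixed = TRUE)
  for (i in seq_along(u))
    out <- gsub(paste0(":T", i, "]"), paste0(":", new[i], "]"), out, fixed = TRUE)
  out
}

# small deterministic fixture datasets
suite_sample <- function(suite, n, seed = NULL, truth = NULL) {
  generate_reactions(builtin_suites()[[suite]], n = n, seed = seed, truth = truth)
}
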