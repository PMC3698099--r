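# Independent oracles and small fixture builders shared across the suite.

# Brute-force double-loop evaluation of the Moran's I formula.
moran_bruteforce <- function(y, W) {
  n <- length(y)
  Y <- mean(y)
  num <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      num <- num + W[i, j] * (y[i] - Y) * (y[j] - Y)
  (n / sum(W)) * num / sum((y - Y)^2)
}

# All permutations of 1..n (n small), one per row.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Brute-force agglomerative clustering; returns the implied cophenetic
# matrix (height at which each pair first shares a cluster).
agglom_bruteforce <- function(m, linkage = "complete") {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  link <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    switch(linkage, complete = max(vals), single = min(vals),
           average = mean(vals))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        h <- link(clusters[[i]], clusters[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    a <- clusters[[best[1L]]]; b <- clusters[[best[2L]]]
    coph[a, b] <- best_h; coph[b, a] <- best_h
    clusters[[best[1L]]] <- c(a, b)
    clusters[[best[2L]]] <- NULL
  }
  coph
}

# A small modification catalog with k synthetic enzymes per attribute.
make_modcat <- function(k = 2L) {
  codes <- attribute_codes()
  modification_catalog(data.frame(
    protein_id = sprintf("E_%s_%d", rep(codes, each = k), seq_len(k)),
    attribute = rep(codes, each = k), stringsAsFactors = FALSE))
}

# In-memory tcm_catalog builder.
make_catalog <- function(ids, natures = NA_character_,
                         flavors = NULL, chemicals = NULL,
                         lineages = NULL) {
  n <- length(ids)
  df <- data.frame(medicinal_id = ids,
                   scientific_name = paste("Sp", ids),
                   nature = rep_len(natures, n),
                   stringsAsFactors = FALSE)
  df$lineage <- if (is.null(lineages)) rep(list(character(0)), n) else lineages
  df$flavors <- if (is.null(flavors)) rep(list(character(0)), n) else flavors
  df$chemical_ids <- if (is.null(chemicals)) rep(list(character(0)), n)
                     else chemicals
  class(df) <- c("tcm_catalog", "data.frame")
  df
}

# Construct a potency_profiles object directly from count matrices.
make_profiles <- function(activating, inhibiting, mode = "count") {
  tcmepi:::new_potency_profiles(rownames(activating), activating,
                                inhibiting, mode)
}

# Zero matrix over the 18 attributes for the given entity ids.
attr_matrix <- function(ids) {
  matrix(0L, length(ids), 18L,
         dimnames = list(ids, attribute_codes()))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

null_config <- function(seed, n = 200L) {
  generator_config(n_medicinals = n, sigma_bm = 0,
                   planted_associations = NULL, homophily_strength = 0,
                   seed = seed)
}
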