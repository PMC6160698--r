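# shared in-code fixtures and independent oracles

# independent O(m^2) Benjamini-Hochberg step-up: q_(i) = min_{j>=i} p_(j)*m/j
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, scaled[i:m])
  }
  q
}

# exhaustive hypergeometric upper tail: enumerate all size-n draws from 1:N
hyper_enumerate <- function(x, K, n_draw, N) {
  draws <- utils::combn(N, n_draw)
  annotated <- colSums(draws <= K)   # genes 1..K are "annotated"
  mean(annotated >= x)
}

# random integrated network over a fixed node universe
random_toy_network <- function(n_edges, seed) {
  set.seed(seed)
  lnc <- sprintf("L%02d", 1:6)
  pcg <- sprintf("P%02d", 1:12)
  mir <- sprintf("miR-%d", 1:4)
  nodes <- data.frame(
    gene = c(lnc, pcg, mir),
    biotype = rep(c("lncRNA", "protein_coding", "miRNA"), c(6, 12, 4)),
    direction = sample(c("up", "down"), 22, TRUE),
    log2_fc = round(stats::rnorm(22), 3), stringsAsFactors = FALSE)
  gpool <- c(lnc, pcg)
  co <- t(replicate(n_edges, sample(gpool, 2)))
  coexpr <- unique(data.frame(
    gene_a = pmin(co[, 1], co[, 2]), gene_b = pmax(co[, 1], co[, 2]),
    sign = sample(c("positive", "negative"), n_edges, TRUE),
    stringsAsFactors = FALSE))
  coexpr <- coexpr[!duplicated(coexpr[, 1:2]), , drop = FALSE]
  pp <- t(replicate(max(2, n_edges %/% 2), sample(pcg, 2)))
  ppi <- unique(data.frame(protein_a = pp[, 1], protein_b = pp[, 2],
                           stringsAsFactors = FALSE))
  mt <- data.frame(mirna = sample(mir, max(2, n_edges %/% 4), TRUE),
                   target = sample(gpool, max(2, n_edges %/% 4), TRUE),
                   stringsAsFactors = FALSE)
  mt <- unique(mt)
  list(nodes = nodes, coexpr = coexpr, ppi = ppi, mirna = mt)
}

# deterministic toy coexpression edge table
toy_edges <- function() {
  data.frame(
    gene_a = c("L1", "L1", "L1", "L1", "P1"),
    gene_b = c("P1", "P2", "P3", "L2", "P2"),
    sign = c("positive", "positive", "negative", "positive", "positive"),
    stringsAsFactors = FALSE)
}

toy_biotype <- function() {
  c(L1 = "lncRNA", L2 = "lncRNA", P1 = "protein_coding",
    P2 = "protein_coding", P3 = "protein_coding")
}
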