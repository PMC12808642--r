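# Independent oracles and small fixtures. These deliberately re-derive
# quantities with plain loops and the closed formulas, so they share no code
# path with the package implementation they check.

# small generator spec: quick to build, still two rings + core
tinySpec <- function(...) {
  args <- modifyList(
    list(innerCount = 4L, outerCount = 6L, innerRadius = 60,
         outerRadius = 105, innerPitchDeg = 90, outerPitchDeg = 60,
         coreChlsPerCore = 10L, coreCount = 1L),
    list(...))
  do.call(syntheticComplexSpec, args)
}

# brute-force different-subunit chlorophyll pairs within cutoff (double loop)
oraclePairs <- function(model, cutoff) {
  p <- pigments(model)
  chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
  xyz <- as.matrix(chl[, c("x", "y", "z")])
  out <- list()
  n <- nrow(chl)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (chl$chain_id[i] == chl$chain_id[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff)
      out[[length(out) + 1]] <- data.frame(
        a = chl$pigment_id[i], b = chl$pigment_id[j], d = d,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(a = character(), b = character(), d = numeric()))
  do.call(rbind, out)
}

# canonical unordered pair key
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# brute-force Forster edges: loops + direct formula evaluation
oracleEdges <- function(model, cutoff = 23, C = 32.26, n_ri = 1.55) {
  p <- pigments(model)
  chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
  xyz <- as.matrix(chl[, c("x", "y", "z")])
  u <- as.matrix(chl[, c("nd_x", "nd_y", "nd_z")]) -
    as.matrix(chl[, c("nb_x", "nb_y", "nb_z")])
  u <- u / sqrt(rowSums(u^2))
  out <- list()
  n <- nrow(chl)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    rv <- xyz[j, ] - xyz[i, ]
    R <- sqrt(sum(rv^2))
    if (R > cutoff) next
    rh <- rv / R
    kap <- sum(u[i, ] * u[j, ]) - 3 * sum(u[i, ] * rh) * sum(u[j, ] * rh)
    rate <- C * kap^2 / (n_ri^4 * (R / 10)^6)
    out[[length(out) + 1]] <- data.frame(
      key = pairKey(chl$pigment_id[i], chl$pigment_id[j]),
      R = R, kappa_sq = kap^2, rate = rate, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(key = character(), R = numeric(),
                      kappa_sq = numeric(), rate = numeric()))
  do.call(rbind, out)
}

# random chlorophyll cloud spread over a few pseudo-chains; positions in a
# slab so pair counts are moderate
randomChlModel <- function(n_pigments, n_chains = 5, box = 60, seed = 1) {
  set.seed(seed)
  chains <- sprintf("X%02d", seq_len(n_chains))
  ch <- sample(chains, n_pigments, replace = TRUE)
  mg <- cbind(runif(n_pigments, 0, box), runif(n_pigments, 0, box),
              runif(n_pigments, -12, 12))
  u <- matrix(rnorm(3 * n_pigments), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  nb <- mg - 2.1 * u
  nd <- mg + 2.1 * u
  pig <- data.frame(
    pigment_id = sprintf("%s:%d:CLA", ch, seq_len(n_pigments)),
    chain_id = ch, residue_number = seq_len(n_pigments),
    residue_name = "CLA", pigment_class = "chlorophyll_a",
    x = mg[, 1], y = mg[, 2], z = mg[, 3],
    nb_x = nb[, 1], nb_y = nb[, 2], nb_z = nb[, 3],
    nd_x = nd[, 1], nd_y = nd[, 2], nd_z = nd[, 3],
    stringsAsFactors = FALSE)
  subs <- data.frame(chain_id = chains, role = "isia",
                     ring = rep(c("inner", "outer"), length.out = n_chains),
                     ring_index = NA_integer_, stringsAsFactors = FALSE)
  # indices must be unique within a ring for validity
  for (rg in c("inner", "outer")) {
    sel <- subs$ring == rg
    subs$ring_index[sel] <- seq_len(sum(sel))
  }
  ComplexModel("random", subs, pig)
}

# random unit vector
runitvec <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# minimal hand-built model: chlorophylls at given Mg positions with given
# dipoles, one per chain by default
chlModel <- function(mg, u = NULL, chains = NULL) {
  mg <- matrix(mg, ncol = 3)
  n <- nrow(mg)
  if (is.null(u)) u <- matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE)
  u <- matrix(u, ncol = 3)
  if (is.null(chains)) chains <- sprintf("C%02d", seq_len(n))
  nb <- mg - 2.1 * u
  nd <- mg + 2.1 * u
  pig <- data.frame(
    pigment_id = sprintf("%s:%d:CLA", chains, 500 + seq_len(n)),
    chain_id = chains, residue_number = 500L + seq_len(n),
    residue_name = "CLA", pigment_class = "chlorophyll_a",
    x = mg[, 1], y = mg[, 2], z = mg[, 3],
    nb_x = nb[, 1], nb_y = nb[, 2], nb_z = nb[, 3],
    nd_x = nd[, 1], nd_y = nd[, 2], nd_z = nd[, 3],
    stringsAsFactors = FALSE)
  uc <- unique(chains)
  subs <- data.frame(chain_id = uc, role = "isia", ring = "none",
                     ring_index = NA_integer_, stringsAsFactors = FALSE)
  ComplexModel("toy", subs, pig)
}
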