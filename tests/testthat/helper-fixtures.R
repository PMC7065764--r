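# Shared in-code fixtures: a tiny two-patch survey with known counts and
# effort, used across effort / forest-dependency / community tests.

toySites <- function() {
  data.frame(site_id = c("P1", "P2", "CF1"),
             site_type = c("patch", "patch", "continuous"),
             area_ha = c(1.4, 100, 144800),
             prox = c(10, 1000, 1e9),
             matrix_complexity = c(2, 5, 10))
}

toyEffort <- function() {
  data.frame(
    site_id = rep(c("P1", "P2"), each = 4),
    stratum = rep(c("forest", "forest", "matrix", "matrix"), 2),
    trap_class = rep(c("live", "pitfall"), 4),
    trap_nights = c(100, 80, 100, 0, 300, 160, 100, 0))
}

toyCaptures <- function() {
  # spA forest-loving, spB matrix-loving, spC pitfall-only
  data.frame(
    site_id = c("P1", "P1", "P2", "P2", "P1", "P2", "P1"),
    stratum = c("forest", "matrix", "forest", "matrix", "forest", "forest",
                "forest"),
    species_id = c("spA", "spA", "spA", "spB", "spB", "spC", "spC"),
    trap_class = c("live", "live", "live", "live", "live", "pitfall",
                   "pitfall"),
    count = c(10, 1, 30, 12, 2, 3, 1))
}

# small standardized abundance matrix with dimnames
toyAbundanceMatrix <- function() {
  matrix(c(30, 10, 0,
           0, 20, 5,
           1, 0, 0),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("spA", "spB", "spC"), c("P1", "P2", "P3")))
}

# random regression design with reproducible seed
randomDesign <- function(n, p, seed) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- paste0("x", seq_len(p))
  beta <- rnorm(p)
  y <- as.numeric(as.matrix(X) %*% beta + rnorm(n))
  list(y = y, X = X, terms = names(X))
}
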