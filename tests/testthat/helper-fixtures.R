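# shared fixtures built in code

# freely jointed chain coordinates, independent of the package generator
fjc_coords <- function(n, bond = 3.8) {
  u <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * bond
  rbind(0, apply(u, 2, cumsum))
}

# closed-form Debye function, the nu = 1/2 oracle
debye_fn <- function(q, rg) {
  x <- q^2 * rg^2
  2 * (exp(-x) + x - 1) / x^2
}

# default instrument-like grids used across tests
nse_q <- c(0.05, 0.08, 0.11, 0.14, 0.17)
nse_t15 <- exp(seq(log(0.1), log(150), length.out = 15))

saxs_grid <- function(n = 120) exp(seq(log(0.01), log(0.7), length.out = n))
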