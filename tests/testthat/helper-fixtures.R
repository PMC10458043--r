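# Small in-code fixtures shared across test files.

tiny_spec <- function(nr = 4, nc = 4, cell = 100, crs = "EPSG:3763") {
  grid_spec(0, nr * cell, cell, nr, nc, crs)
}

tiny_layer <- function(values, name = "L", kind = "continuous",
                       cell = 100) {
  values <- as.matrix(values)
  grid_layer(tiny_spec(nrow(values), ncol(values), cell), values,
             name = name, kind = kind)
}

# deterministic continuous stack of k layers on an nr x nc grid
tiny_stack <- function(nr = 6, nc = 6, k = 2, seed = 42) {
  withr::with_seed(seed, {
    layers <- lapply(seq_len(k), function(i)
      tiny_layer(matrix(rnorm(nr * nc), nr, nc), name = paste0("L", i)))
  })
  raster_stack(layers)
}

# tiny presence/background set with a clear signal on variable "a":
# presences sit at high a, background spans the range
tiny_pb <- function(m = 5, nbg = 10, seed = 7) {
  withr::with_seed(seed, {
    bg <- data.frame(a = seq(0, 1, length.out = nbg),
                     b = runif(nbg))
    p <- data.frame(a = seq(0.8, 1, length.out = m),
                    b = runif(m))
  })
  list(presence = p, background = bg)
}

# direct (textbook) regularized-gain evaluation used as a fitting oracle;
# replicates the model's feature normalization but nothing of its optimizer
gain_direct <- function(lambda, Fp, Fbg, beta) {
  eta_p <- as.numeric(Fp %*% lambda)
  eta_b <- as.numeric(Fbg %*% lambda)
  mx <- max(eta_b)
  mean(eta_p) - (mx + log(sum(exp(eta_b - mx)))) + log(nrow(Fbg)) -
    sum(beta * abs(lambda))
}
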