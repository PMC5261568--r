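# Small fixtures shared across tests; everything is built in code.

tinyGrid <- function() seq(1500, 1800, by = 4)

# Single-Gaussian profile, deterministic (no jitter, no noise)
pureProfile <- function(center = 1650, fwhm = 28, amplitude = 1,
                        name = "normal_epidermis") {
  classProfile(name, bandComponents(center, fwhm, amplitude),
               amplitudeCv = 0, noiseSd = 0)
}

# A small study design for fast end-to-end tests
smallDesign <- function(seed = 42L) {
  studyDesign(
    pcaCal = c(electrical_mark = 8, normal_epidermis = 10),
    plsCal = c(electrical_mark = 8, normal_epidermis = 8,
               normal_dermis = 8),
    internalPred = c(electrical_mark = 4, normal_epidermis = 4,
                     normal_dermis = 4),
    externalVal = c(electrical_mark = 5, normal_epidermis = 5,
                    normal_dermis = 4),
    seed = seed)
}

# Brute-force EMSC oracle: explicit normal-equations solve on the
# [1, m, nu*, nu*^2] design
emscOracle <- function(z, m, nuStar) {
  D <- cbind(1, m, nuStar, nuStar^2)
  unname(drop(solve(t(D) %*% D, t(D) %*% z)))
}

# Brute-force Savitzky-Golay oracle: refit the local polynomial in one
# window and differentiate it twice at the centre
sgOracle <- function(values, i, window = 9L, order = 3L, h = 1) {
  k <- (window - 1L) %/% 2L
  idx <- (i - k):(i + k)
  x <- idx - i
  fit <- lm(values[idx] ~ poly(x, order, raw = TRUE))
  2 * coef(fit)[[3L]] / h^2
}
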