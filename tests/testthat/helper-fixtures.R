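# small in-code fixtures shared across test files

.toy_cohort <- function(n, seed = 99) {
  set.seed(seed)
  data.frame(
    PATNO = seq_len(n),
    AGE = round(rnorm(n, 62, 8), 1),
    SEX = sample(c("M", "F"), n, TRUE),
    ETHNICITY = sample(c("not_hispanic", "hispanic"), n, TRUE, c(0.95, 0.05)),
    RACE = sample(c("white", "black", "asian", "other"), n, TRUE),
    HANDED = sample(c("right", "left", "mixed"), n, TRUE, c(0.85, 0.12, 0.03)),
    EDUCYRS = sample(10:20, n, TRUE),
    DXDUR = sample(100:1500, n),
    SYMPDUR = sample(200:2000, n),
    DOMSIDE = sample(c("right", "left", "symmetric"), n, TRUE),
    GDS = sample(0:10, n, TRUE),
    MOCA = sample(20:30, n, TRUE),
    TREMOR = rbinom(n, 1, 0.8),
    RIGIDITY = rbinom(n, 1, 0.7),
    POSTINST = rbinom(n, 1, 0.3),
    PAG_NAME = "NUPDRS3A",
    stringsAsFactors = FALSE)
}

# linear-model regression fixture with known structure
.toy_regression <- function(n = 40, p = 6, r2 = 0.6, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- c(3, -2, 1.5, rep(0, p - 3))
  eta <- as.numeric(X %*% beta)
  s <- sqrt(var(eta) * (1 - r2) / r2)
  y <- eta + rnorm(n, 0, s)
  list(X = feature_matrix(X, rep("imaging", p), rep(TRUE, p)),
       y = y, eta = eta, beta = beta)
}
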