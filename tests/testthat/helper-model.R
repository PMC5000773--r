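# Shared fixtures: everything is generated in code at test time.

# Short protocol (one maternal block, two fetal sub-blocks) for tests that
# exercise mechanics rather than the full experimental design.
shortProtocol <- function() {
  flowProtocol(maternalFlows = 14e-3, fetalFlows = c(3e-3, 9e-3),
               subBlockDuration = 10, baselineDuration = 10,
               washDuration = 0, sampleOffsets = c(5, 8))
}

# Random non-negative flux-law inputs with Tot >= A (A is counted in Tot).
randomCarrierCase <- function() {
  A_I <- runif(1, 0, 2); A_II <- runif(1, 0, 2)
  R_I <- runif(1, 0, 3); R_II <- runif(1, 0, 3)
  list(A_I = A_I, A_II = A_II, R_I = R_I, R_II = R_II,
       Tot_I = A_I + R_I, Tot_II = A_II + R_II,
       V = runif(1, 0.1, 2), K = runif(1, 0.01, 2))
}

randomState <- function() {
  s <- abs(rnorm(5, sd = c(1e-9, 1e-7, 1e-9, 1e-3, 1e-4)))
  names(s) <- c("A_m", "A_s", "A_f", "C_m", "C_f")
  s
}

# Hand-built dataset for direct ANOVA checks (no simulation involved).
manualDataset <- function(responseFun, nPlacentas = 5, sd = 0) {
  Fm <- c(10, 14, 18) * 1e-3
  Ff <- c(3, 6, 9) * 1e-3
  grid <- expand.grid(placenta = seq_len(nPlacentas), F_m_nominal = Fm,
                      F_f_nominal = Ff, offset = c(15, 18))
  grid$is_baseline <- FALSE
  mu <- responseFun(grid$F_m_nominal, grid$F_f_nominal)
  grid$uptake <- mu + rnorm(nrow(grid), sd = sd)
  grid$transfer <- grid$uptake
  list(samples = grid)
}
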