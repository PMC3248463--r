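# Small fixtures built in code; kept tiny so each test runs in seconds.

tiny_panel <- function() {
  snp_panel(c("rs1", "rs2", "rs3"),
            effect_allele = c("A", "C", "G"),
            other_allele = c("G", "T", "A"),
            beta = c(0.1, -0.05, 0.02),
            se = c(0.01, 0.008, 0.012),
            eaf = c(0.5, 0.3, 0.8))
}

uniform_panel <- function(n = 160, beta = 0.05, eaf = 0.3) {
  snp_panel(sprintf("s%03d", seq_len(n)), "A", "G",
            beta = beta, se = 0.007, eaf = eaf)
}

# Allele-mixture tail odds recomputed from first principles (independent of
# the package's internals, used as the analytic oracle).
oracle_tail_odds <- function(beta, p, cutoff, upper) {
  mi <- beta * p; md <- -beta * (1 - p)
  s <- sqrt(1 - beta^2 * p * (1 - p))
  pi <- pnorm(cutoff, mi, s, lower.tail = !upper)
  pd <- pnorm(cutoff, md, s, lower.tail = !upper)
  p * pi / ((1 - p) * pd)
}
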