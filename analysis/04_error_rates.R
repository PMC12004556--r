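#!/usr/bin/env Rscript
# The error-rate simulation that motivates sequential monitoring of
# meta-analyses: under a null effect, testing the cumulative z-curve
# against a fixed 1.96 threshold after every added trial inflates the
# type-I error well above alpha, while the alpha-spending boundaries
# keep it near alpha; under the design effect, monitoring retains the
# planned power once the required information size is reached.
# 1,000 replicates per scenario; 10 equal trials spanning the design
# RIS (p_C = 0.1, RRR 20% -> 6,429 participants -> 322 per arm per
# trial); z-curves evaluated at the generating tau2.

suppressMessages(library(tsasens))

n_rep <- 1000
cfg <- tsa_config(estimator = "DL")
spec_null <- simulation_spec(k = 10, theta = 0, tau2 = 0,
                             p_control = 0.1, n_range = 322L, seed = 1)
mu <- implied_log_or(0.1, 0.2)
spec_eff <- simulation_spec(k = 10, theta = -mu, tau2 = 0,
                            p_control = 0.1, n_range = 322L, seed = 2)

null_tsa <- simulate_error_rates(spec_null, cfg, n_rep, "tsa_boundaries",
                                 tau2_fixed = 0, seed = 101)
null_naive <- simulate_error_rates(spec_null, cfg, n_rep, "naive_repeated",
                                   tau2_fixed = 0, seed = 101)
power_tsa <- simulate_error_rates(spec_eff, cfg, n_rep, "tsa_boundaries",
                                  tau2_fixed = 0, seed = 202)
# the practical procedure: tau2 re-estimated at every look (conservative)
null_reest <- simulate_error_rates(spec_null, cfg, n_rep, "tsa_boundaries",
                                   seed = 101)

tab <- data.frame(
  scenario = c("null, TSA boundaries", "null, naive repeated 1.96",
               "design effect, TSA boundaries",
               "null, TSA boundaries (tau2 re-estimated)"),
  truth = c("theta = 0", "theta = 0", sprintf("theta = -%.4f", mu),
            "theta = 0"),
  nominal = c(0.05, 0.05, 0.80, 0.05),
  crossing = c(null_tsa$proportion, null_naive$proportion,
               power_tsa$proportion, null_reest$proportion),
  n_replicates = n_rep)
tab$mc_se <- sqrt(tab$crossing * (1 - tab$crossing) / n_rep)
print(tab, row.names = FALSE, digits = 3)

cat(sprintf("\nnaive repeated testing inflates the null crossing %.1f-fold\n",
            null_naive$proportion / null_tsa$proportion))

dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, file.path("results", "error_rates.csv"),
                 row.names = FALSE)
cat("written to results/error_rates.csv\n")
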