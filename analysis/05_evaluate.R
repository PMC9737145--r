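#!/usr/bin/env Rscript
# Model evaluation: Rc2/RMSEC on the calibration set, Rv2/RMSEP/RPD on the
# validation set, for every chemical group and every pre-treatment (the
# grid-searched SNV bundles from 04, plus raw/D1/SS full-spectrum forests for
# the pre-treatment comparison).
#
# Reads:  results/bundles/ (from 04_select_fit.R)
# Writes: results/report.csv (group-range-method table),
#         results/prediction_scatter.csv

suppressPackageStartupMessages(library(aromahsi))
SEED <- 1L
if (!dir.exists("results/bundles"))
  stop("run analysis/04_select_fit.R first")

gen <- generate_spectra(synthetic_config(seed = SEED))
sp <- split_samples(gen$matrix$sample_ids, seed = SEED + 3000L)
groups <- c("ester", "aldehyde", "ketone", "alcohol")

reports <- list()
scatter <- list()
for (g in groups) {
  y <- stats::setNames(gen$truth[[g]], gen$truth$sample_id)
  m_snv <- snv(gen$matrix)
  bundle <- load_bundle(file.path("results", "bundles", g))
  reports[[paste(g, "snv")]] <- evaluate_model(bundle, sp, m_snv, y)
  scatter[[g]] <- cbind(group = g,
                        prediction_scatter(bundle, sp, m_snv, y))

  # pre-treatment comparison on the full spectrum
  for (method in c("raw", "d1", "ss")) {
    pp <- preprocess_apply(gen$matrix, method,
                           calibration = subset_samples(gen$matrix,
                                                        sp$calibration))
    Xc <- subset_samples(pp$matrix, sp$calibration)
    b <- fit_rf_model(Xc, y[sp$calibration],
                      manual_selection(Xc, num_trees = 300),
                      seed = SEED + 5000L, target = g, ss_state = pp$state)
    reports[[paste(g, method)]] <- evaluate_model(b, sp, pp$matrix, y)
  }
}
all_reports <- do.call(rbind, reports)
write_report_csv(all_reports, "results/report.csv")
write.csv(do.call(rbind, scatter), "results/prediction_scatter.csv",
          row.names = FALSE)

fmt <- all_reports
fmt[c("Rc2", "Rv2")] <- round(fmt[c("Rc2", "Rv2")], 3)
fmt[c("RMSEC", "RMSEP", "RPD")] <- round(fmt[c("RMSEC", "RMSEP", "RPD")], 2)
print(fmt[c("target", "method", "Rc2", "RMSEC", "Rv2", "RMSEP", "RPD")],
      row.names = FALSE)
cat("wrote results/report.csv\n")
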