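#!/usr/bin/env Rscript
# Preprocess the raw catch table into the annual series the models use:
# CPUE -> completeness filter (>= 50%) -> natural log with per-series zero
# offset -> 2-SD outlier interpolation -> seasonal-window annual means
# (May-Oct for age-0, Feb-May for age-1+), and the standardized Jan-Jun
# flow covariate.
#
# Reads:  results/catch.csv, results/stations.csv, results/flow.csv
# Writes: results/annual_<gear>_<age>.csv, results/labels_<age>.csv,
#         results/flow_covariate.csv, results/cleaning_report.json

library(flowssm)

catch <- read_catch_table("results/catch.csv", "results/stations.csv")
stations <- read.csv("results/stations.csv")
flow <- read_flow("results/flow.csv")

years <- min(catch$year):max(catch$year)
fa <- annual_flow(flow, months = 1:6, years = years)
cov <- standardize_flow(fa)
write.csv(data.frame(year = years, outflow_jan_jun = as.numeric(fa),
                     covariate = cov),
          "results/flow_covariate.csv", row.names = FALSE)

report <- list()
for (age in c("age0", "age1plus")) {
  annual <- NULL; labels <- NULL
  for (gear in c("midwater", "otter")) {
    prep <- prepare_annual_cpue(catch, stations, gear, age)
    annual <- rbind(annual, prep$annual)
    labels <- rbind(labels, prep$labels)
    report[[paste(gear, age, sep = "_")]] <- list(
      dropped = prep$report$dropped,
      n_retained = nrow(prep$annual),
      replacements = sum(prep$report$replacements),
      replaced_pct = round(100 * sum(prep$report$replacements) /
                             sum(!is.na(prep$monthly)), 2))
    write.csv(data.frame(series_id = rownames(prep$annual), prep$annual,
                         check.names = FALSE),
              sprintf("results/annual_%s_%s.csv", gear, age),
              row.names = FALSE)
  }
  write.csv(labels, sprintf("results/labels_%s.csv", age), row.names = FALSE)
  message(sprintf("%s: %d series retained; outlier replacements %s%%",
                  age, nrow(annual),
                  paste(sapply(report[grep(age, names(report))],
                               `[[`, "replaced_pct"), collapse = "/")))
}
jsonlite::write_json(report, "results/cleaning_report.json",
                     auto_unbox = TRUE, digits = NA)
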