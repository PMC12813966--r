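#!/usr/bin/env Rscript
# Compare the six spatial-structure hypotheses (single estuary-wide state;
# gear; region; region x gear; lateral habitat; lateral x vertical
# habitat) by AICc for each age class, and extract the smoothed
# observation-error-free states of the winning structure.
#
# Reads:  results/annual_*.csv, results/labels_*.csv
# Writes: results/structure_<age>.csv, results/states_<age>.csv

library(flowssm)

read_annual <- function(age) {
  parts <- lapply(c("midwater", "otter"), function(g) {
    d <- read.csv(sprintf("results/annual_%s_%s.csv", g, age),
                  check.names = FALSE)
    m <- as.matrix(d[, -1]); rownames(m) <- d$series_id
    m
  })
  do.call(rbind, parts)
}

for (age in c("age0", "age1plus")) {
  y <- read_annual(age)
  labels <- read.csv(sprintf("results/labels_%s.csv", age))
  labels <- labels[match(rownames(y), labels$series_id), ]

  tab <- compare_hypotheses(y, labels)
  write.csv(tab, sprintf("results/structure_%s.csv", age), row.names = FALSE)
  best <- tab$hypothesis[1]
  message(sprintf("%s: best structure %s (%d states), runner-up dAICc = %.1f",
                  age, best, tab$n_states[1], tab$dAICc[2]))

  fit <- attr(tab, "fits")[[best]]
  st <- extract_states(fit)
  write.csv(data.frame(group = rownames(st$mean), st$mean,
                       check.names = FALSE),
            sprintf("results/states_%s.csv", age), row.names = FALSE)
  write.csv(data.frame(group = rownames(st$se), st$se, check.names = FALSE),
            sprintf("results/states_se_%s.csv", age), row.names = FALSE)
}
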