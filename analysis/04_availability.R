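#!/usr/bin/env Rscript

## Stage 4 — fit each individual's central-place CRW movement model to its
## cleaned trajectory and generate availability data (10 random positions
## per used position, same autocorrelation structure), then attach land
## cover and distance covariates to the stacked used/available table.

suppressPackageStartupMessages(library(owltrack))

out <- "results/availability"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read.csv("results/simulated/individuals.csv")
nests <- setNames(lapply(seq_len(nrow(meta)), function(i)
  c(meta$nest_x[i], meta$nest_y[i])), meta$id)
map <- read_landcover_geojson("results/simulated/landcover.geojson")
clean <- read_fixes("results/clean/clean_fixes.csv")

used <- list(); avail <- list()
for (id in meta$id) {
  tr <- clean[clean$id == id, ]
  segs <- segment_nights(tr)$segments
  tr <- do.call(rbind, lapply(segs, function(s) s$fixes))
  fit <- fit_crw_params(tr, nests[[id]], seed = match(id, meta$id))
  jsonlite::write_json(
    list(id = id, turn_concentration = fit$turn_concentration,
         attraction_exponent = fit$attraction_exponent,
         dmax_m = fit$dmax_m, objective = attr(fit, "objective")),
    file.path(out, paste0(id, "_crw_params.json")), auto_unbox = TRUE)
  message(sprintf("%s: kappa %.2f, gamma %.2f, dmax %.0f m (J = %.3f)",
                  id, fit$turn_concentration, fit$attraction_exponent,
                  fit$dmax_m, attr(fit, "objective")))
  used[[id]] <- tr
  avail[[id]] <- generate_availability(
    tr, fit, nests[[id]], multiplier = 10,
    night_lengths = vapply(segs, function(s) s$n_fixes, integer(1)))
}
tab <- used_available_table(do.call(rbind, used), do.call(rbind, avail),
                            map, nests)
write.csv(tab, file.path(out, "used_available.csv"), row.names = FALSE)
message(sprintf("used/available table: %d used, %d available",
                sum(tab$used == 1), sum(tab$used == 0)))

## territory descriptions around each nest
terr <- do.call(rbind, lapply(meta$id, function(id) {
  data.frame(id = id,
             mean_field_size_ha = mean_field_size(map, nests[[id]]),
             simpson_d = simpson_diversity(map, nests[[id]]))
}))
write.csv(terr, file.path(out, "territories.csv"), row.names = FALSE)
comp <- do.call(rbind, lapply(meta$id, function(id)
  cbind(id = id, buffer_composition(nests[[id]], map))))
write.csv(comp, file.path(out, "buffer_composition.csv"), row.names = FALSE)
message(sprintf("territories: field size %.1f +- %.1f ha, Simpson D %.2f +- %.2f",
                mean(terr$mean_field_size_ha), sd(terr$mean_field_size_ha),
                mean(terr$simpson_d), sd(terr$simpson_d)))
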