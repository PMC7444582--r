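# shared CLI chain fixture used by the CLI and acceptance suites
md5_of <- function(...) unname(tools::md5sum(file.path(...)))

run_full_chain <- function(root, seed) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  sim_dir <- file.path(root, "sim")
  cli_main(c("simulate", "--preset", "kin2_kd", "--duration", "240",
             "--seed", as.character(seed), "--out", sim_dir,
             "--height", "20", "--width", "200"))
  cli_main(c("register", "--in", file.path(sim_dir, "movie.tif"),
             "--out", file.path(root, "reg.tif"),
             "--max-shift", "4",
             "--shifts", file.path(root, "shifts.csv")))
  cli_main(c("extract", "--in", file.path(root, "reg.tif"),
             "--roi", "0,0,20,200", "--entry", "30",
             "--trace", file.path(root, "trace.csv"),
             "--kymo", file.path(root, "kymo.csv")))
  cli_main(c("peaks", "--trace", file.path(root, "trace.csv"),
             "--metrics", file.path(root, "metrics.json"),
             "--peaks", file.path(root, "peaks.csv")))
  ev <- data.frame(ovulation_id = "ov1", entry_start = 30, neck_close = 75,
                   valve_open = NA, valve_close = NA, exited = FALSE,
                   returned = FALSE, observation_end = 239)
  write.csv(ev, file.path(root, "events.csv"), row.names = FALSE)
  cli_main(c("transits", "--events", file.path(root, "events.csv"),
             "--dt", "1", "--out", file.path(root, "transits.csv")))
  pop <- data.frame(condition = rep(c("control", "kd"), each = 20),
                    category = c(rep("occupied", 18), rep("unoccupied", 2),
                                 rep("occupied", 5), rep("unoccupied", 15)))
  write.csv(pop, file.path(root, "population.csv"), row.names = FALSE)
  cli_main(c("stats", "--population", file.path(root, "population.csv"),
             "--control", "control", "--out", file.path(root, "stats.csv")))
  root
}
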