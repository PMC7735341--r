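#!/usr/bin/env Rscript
# Summarises duty-cycled file logs (96 files of 630 s per day) into the
# daily percentage of song-bearing files per site, and applies the
# cessation rule: song presence ends on the last day with song that is
# followed by five consecutive fully recorded song-free days across all
# sites. Demonstrated on a simulated three-site northbound migration
# season.

suppressPackageStartupMessages(library(songculture))

set.seed(2016)
season <- function(peak_day, n_days, scale = 35) {
  p <- scale * exp(-((seq_len(n_days) - peak_day) / 12)^2)
  p[p < 1.5] <- 0
  p
}
n_days <- 75
logs <- rbind(
  simulate_file_log("Kaikoura", "2016-06-04", season(25, n_days), seed = 1),
  simulate_file_log("CookStrait", "2016-06-04", season(32, n_days), seed = 2),
  simulate_file_log("STB", "2016-06-04", season(35, n_days, 60), seed = 3))

daily <- daily_presence(logs)
cat("Daily presence summary over", length(unique(daily$site)), "sites,",
    nrow(daily), "site-days\n")
peak <- daily[which.max(daily$percent), ]
cat(sprintf("Peak: %s on %s with %.1f%% of files containing song\n",
            peak$site, format(peak$date), peak$percent))

res <- cessation_date(daily)
if (res$ceased) {
  cat("Song presence ceased after", format(res$last_presence),
      sprintf("(followed by %d clear full days)\n", res$clear_run))
} else {
  cat("No cessation date: record",
      if (res$censored) "right-censored" else "contains no presence", "\n")
}

write_daily_presence(daily, "results/daily_presence.csv")
cat("wrote results/daily_presence.csv\n")
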