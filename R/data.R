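#' Benchmark haul-video summary
#'
#' Durations, ground-truth Norway lobster counts, arrival rates and native
#' frame rates of the five benchmark haul videos that define the study
#' conditions this package emulates (sparse arrivals of ~0.06-0.08
#' objects/s on a 60 FPS camera). The synthetic scene generator's defaults
#' are anchored to this regime.
#'
#' @return A `data.frame` with columns `video`, `duration_s`, `gt_count`,
#'   `rate_per_s`, `fps`.
#' @examples
#' v <- benchmark_videos()
#' sum(v$gt_count)
#' @export
benchmark_videos <- function() {
  utils::read.csv(system.file("extdata", "benchmark_videos.csv",
                              package = "trawlcount"),
                  stringsAsFactors = FALSE)
}
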