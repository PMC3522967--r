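# The week-long reference simulation used by the pipeline-level checks:
# 7 days at 6 images/hour (1,008 frames), 16 h/8 h photoperiod, default
# organ (30 x 20 px semi-axes growing 0.05 px/frame, 4 px/24-frame
# nutation) in a 240 x 320 px frame, two-camera jump emulation on.
# Built once per test run and cached.
weekRunCache <- new.env(parent = emptyenv())

weekRun <- function(noiseSd = 0, seed = 5) {
  key <- sprintf("n%g_s%d", noiseSd, seed)
  if (!is.null(weekRunCache[[key]])) return(weekRunCache[[key]])
  plan <- experimentPlan(days = 7, imagesPerHour = 6)
  org <- organModel(center = c(160, 120))
  il <- illuminationModel(noiseSd = noiseSd)
  sq <- simulateSequence(org, il, plan, seed = seed, size = c(240, 320))
  tr <- trackSequence(sq, userRect = c(100, 60, 220, 180), pipelineConfig(),
                      mgx = 8, mgy = 12)
  out <- list(seq = sq, track = tr)
  weekRunCache[[key]] <- out
  out
}
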