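## Battery-wide vocabulary: the eight active tests, their nominal durations,
## per-test feature names and units, and the tests repeated per hand.

HD_TESTS <- c("sdmt", "swr", "tapping", "draw", "chorea", "balance",
              "uturn", "walking")

HD_STUDIES <- c("OLE", "HD_NHS", "DIGITAL_HD")
HD_COHORTS <- c("control", "premanifest", "manifest")

## Nominal test durations in seconds.
HD_TEST_DURATION <- c(sdmt = 90, swr = 45, tapping = 30, draw = 30,
                      chorea = 30, balance = 30, uturn = 60, walking = 120)

## Tests administered once per hand.
HD_HANDED_TESTS <- c("tapping", "draw", "chorea")

## Ambulatory tests that require the phone in the waist pouch.
HD_POUCH_TESTS <- c("balance", "uturn", "walking")

## Weekly (rather than daily) tests; administered on days 1, 8, 15, 22.
HD_WEEKLY_TESTS <- c("sdmt", "swr")
HD_WEEKLY_DAYS <- c(1L, 8L, 15L, 22L)
HD_STUDY_DAYS <- 28L

HD_FEATURE_OF_TEST <- c(sdmt = "sdmt_correct", swr = "swr_correct",
                        tapping = "intertap_mean_ms", draw = "spiral_speed_cv",
                        chorea = "sway_path", balance = "sway_path",
                        uturn = "turn_speed_median",
                        walking = "step_freq_variance")

HD_FEATURE_UNITS <- c(sdmt_correct = "count", swr_correct = "count",
                      intertap_mean_ms = "ms", spiral_speed_cv = "unitless",
                      sway_path = "m/s^2", turn_speed_median = "rad/s",
                      step_freq_variance = "Hz^2")

## Minimum number of QC-passing observations per two-week interval before the
## interval median is reported (otherwise the interval is missing).
HD_NMIN <- c(sdmt = 1L, swr = 1L, tapping = 3L, draw = 3L, chorea = 3L,
             balance = 3L, uturn = 3L, walking = 3L)

## Uniform resampling rate used for all IMU-based features.
HD_IMU_FS <- 50

## SWR display length: 60 colour words per administration.
HD_SWR_WORDS <- 60L
HD_SWR_VOCAB <- c("red", "green", "blue", "yellow")

## Digital SDMT: 9 abstract symbols mapped to digits 1-9; three key sets.
HD_SDMT_SYMBOLS <- paste0("sym", 1:9)
HD_SDMT_KEYS <- list(
  stats::setNames(1:9, HD_SDMT_SYMBOLS),
  stats::setNames(c(5, 3, 8, 1, 9, 2, 7, 4, 6), HD_SDMT_SYMBOLS),
  stats::setNames(c(2, 9, 4, 7, 1, 8, 3, 6, 5), HD_SDMT_SYMBOLS)
)
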