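#' The eGeMAPS v02 acoustic feature schema
#'
#' Returns the canonical, ordered list of the 88 functional names of the
#' extended Geneva Minimalistic Acoustic Parameter Set, version 02, as
#' emitted by the openSMILE toolkit. All acoustic feature tables handled by
#' the package are reordered to this schema when complete.
#'
#' @return Character vector of length 88 with no duplicates.
#' @seealso [key_acoustic_features()] for the seven features the synthetic
#'   generator plants group effects on by default.
#' @export
#' @examples
#' length(acoustic_schema())
acoustic_schema <- function() {
  c(
    # F0 (semitone scale) and loudness: 10 functionals each
    paste0("F0semitoneFrom27.5Hz_sma3nz_",
           c("amean", "stddevNorm", "percentile20.0", "percentile50.0",
             "percentile80.0", "pctlrange0-2", "meanRisingSlope",
             "stddevRisingSlope", "meanFallingSlope", "stddevFallingSlope")),
    paste0("loudness_sma3_",
           c("amean", "stddevNorm", "percentile20.0", "percentile50.0",
             "percentile80.0", "pctlrange0-2", "meanRisingSlope",
             "stddevRisingSlope", "meanFallingSlope", "stddevFallingSlope")),
    "spectralFlux_sma3_amean", "spectralFlux_sma3_stddevNorm",
    paste0(rep(paste0("mfcc", 1:4, "_sma3_"), each = 2),
           c("amean", "stddevNorm")),
    "jitterLocal_sma3nz_amean", "jitterLocal_sma3nz_stddevNorm",
    "shimmerLocaldB_sma3nz_amean", "shimmerLocaldB_sma3nz_stddevNorm",
    "HNRdBACF_sma3nz_amean", "HNRdBACF_sma3nz_stddevNorm",
    "logRelF0-H1-H2_sma3nz_amean", "logRelF0-H1-H2_sma3nz_stddevNorm",
    "logRelF0-H1-A3_sma3nz_amean", "logRelF0-H1-A3_sma3nz_stddevNorm",
    paste0(rep(paste0("F", rep(1:3, each = 3),
                      c("frequency", "bandwidth", "amplitudeLogRelF0"),
                      "_sma3nz_"), each = 2),
           c("amean", "stddevNorm")),
    "alphaRatioV_sma3nz_amean", "alphaRatioV_sma3nz_stddevNorm",
    "hammarbergIndexV_sma3nz_amean", "hammarbergIndexV_sma3nz_stddevNorm",
    "slopeV0-500_sma3nz_amean", "slopeV0-500_sma3nz_stddevNorm",
    "slopeV500-1500_sma3nz_amean", "slopeV500-1500_sma3nz_stddevNorm",
    "spectralFluxV_sma3nz_amean", "spectralFluxV_sma3nz_stddevNorm",
    paste0(rep(paste0("mfcc", 1:4, "V_sma3nz_"), each = 2),
           c("amean", "stddevNorm")),
    "alphaRatioUV_sma3nz_amean", "hammarbergIndexUV_sma3nz_amean",
    "slopeUV0-500_sma3nz_amean", "slopeUV500-1500_sma3nz_amean",
    "spectralFluxUV_sma3nz_amean",
    "loudnessPeaksPerSec", "VoicedSegmentsPerSec",
    "MeanVoicedSegmentLengthSec", "StddevVoicedSegmentLengthSec",
    "MeanUnvoicedSegmentLength", "StddevUnvoicedSegmentLength",
    "equivalentSoundLevel_dBp"
  )
}

#' The seven key acoustic discriminators
#'
#' Canonical schema names of the seven acoustic features most strongly
#' associated with amyloid positivity in speech: third and second formant
#' bandwidth summaries, the unvoiced Hammarberg index, the H1-A3 harmonic
#' difference, voiced spectral-flux variability, and the mean and standard
#' deviation of voiced-segment length. These are the default planted
#' informative features of [generate_cohort()].
#'
#' @return Character vector of length 7, a subset of [acoustic_schema()].
#' @export
key_acoustic_features <- function() {
  c(
    "F3bandwidth_sma3nz_stddevNorm",     # F3 bandwidth (voiced), CoV
    "F2bandwidth_sma3nz_amean",          # F2 bandwidth (voiced), mean
    "hammarbergIndexUV_sma3nz_amean",    # Hammarberg index (unvoiced), mean
    "logRelF0-H1-A3_sma3nz_amean",       # harmonic difference H1-A3, mean
    "spectralFluxV_sma3nz_stddevNorm",   # spectral flux (voiced), CoV
    "MeanVoicedSegmentLengthSec",        # voiced-segment length, mean
    "StddevVoicedSegmentLengthSec"       # voiced-segment length, std
  )
}

#' Neuropsychological battery schema
#'
#' The 13 neuropsychological scores used as model inputs: WAIS-III
#' similarities and digit spans, WMS-III word-list delayed recall and
#' recognition, the 15-Objects test, Poppelreuter overlapping figures, the
#' SKT automatic-inhibition time, phonetic and semantic verbal fluency, the
#' 15-item Boston Naming Test, verbal comprehension, and Luria's clock test.
#' The MMSE is carried in cohort tables as a clinical descriptor but is not
#' part of the modeling battery.
#'
#' @return Character vector of length 13.
#' @export
neuropsych_schema <- function() {
  c("wais_digit_forward", "wais_digit_backward", "wms_delayed_recall",
    "wms_recognition", "objects_15", "poppelreuter", "skt_time",
    "phonetic_fluency", "semantic_fluency", "wais_similarities",
    "bnt_15", "verbal_comprehension", "luria_clock")
}

#' Default per-group cohort parameters
#'
#' Mean and SD of age, education and each neuropsychological score, and the
#' proportion of females, for the amyloid-positive and amyloid-negative
#' groups of a memory-clinic MCI cohort. Used as the default `group_params`
#' of [synth_config()]; every value is overridable.
#'
#' @return A data.frame with columns `variable`, `mean_pos`, `sd_pos`,
#'   `mean_neg`, `sd_neg`, `lower`, `upper` (truncation bounds; proportions
#'   for `sex_female` are carried in the mean columns with SD `NA`).
#' @export
default_group_params <- function() {
  d <- rbind(
    c("age",                  76.8,  4.5, 69.4, 10.6,  40, 105),
    c("education",             7.4,  4.3, 10.6,  4.5,   0,  30),
    c("sex_female",            0.633, NA, 0.682,  NA,   0,   1),
    c("mmse",                 26.5,  2.3, 27.7,  2.8,   0,  30),
    c("wais_digit_forward",    6.4,  0.9,  7.0,  1.9,   0,  16),
    c("wais_digit_backward",   3.7,  1.1,  4.4,  1.6,   0,  14),
    c("wms_delayed_recall",    1.2,  1.7,  3.2,  2.2,   0,  12),
    c("wms_recognition",      18.4,  3.6, 21.0,  2.4,   0,  24),
    c("objects_15",            9.4,  3.1, 11.3,  2.4,   0,  15),
    c("poppelreuter",          9.1,  1.1,  9.5,  0.8,   0,  10),
    c("skt_time",             40.7, 16.2, 32.0, 12.2,   1, 180),
    c("phonetic_fluency",      9.4,  5.0, 11.9,  3.8,   0,  40),
    c("semantic_fluency",     11.6,  4.8, 14.4,  4.8,   0,  40),
    c("wais_similarities",     7.8,  2.8, 10.8,  3.0,   0,  19),
    c("bnt_15",               12.3,  2.5, 14.1,  1.2,   0,  15),
    c("verbal_comprehension",  5.7,  0.5,  5.8,  0.3,   0,   6),
    c("luria_clock",           3.0,  1.1,  3.2,  1.1,   0,   4)
  )
  out <- data.frame(
    variable = d[, 1],
    mean_pos = as.numeric(d[, 2]), sd_pos = as.numeric(d[, 3]),
    mean_neg = as.numeric(d[, 4]), sd_neg = as.numeric(d[, 5]),
    lower = as.numeric(d[, 6]), upper = as.numeric(d[, 7]),
    stringsAsFactors = FALSE
  )
  out
}
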