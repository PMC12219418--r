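#' Shanxi land-transfer probability matrices
#'
#' The 6x6 row-stochastic transfer matrices for the three simulation
#' scenarios: natural development (NDS), farmland protection (FPS) and
#' accelerated economic development (AEDS), as published for Shanxi
#' Province (1980-2020 transfer law, applied as the 2020-2040 kernel).
#'
#' @param scenario One of "NDS", "FPS", "AEDS".
#' @return A [transition_matrix()].
#' @export
shanxi_transition_matrix <- function(scenario = c("NDS", "FPS", "AEDS")) {
  scenario <- match.arg(scenario)
  f <- system.file("extdata",
                   sprintf("transition_%s.csv", tolower(scenario)),
                   package = "esbundles", mustWork = TRUE)
  df <- utils::read.csv(f, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  transition_matrix(m)
}

#' Shanxi per-unit-area ecosystem service value coefficients
#'
#' The locally adjusted equivalent-factor coefficient table for Shanxi
#' Province: 11 services x 6 land types, in yuan/hm2, based on the
#' standard unit equivalent E_a = 1031.93 yuan/hm2. The construction-land
#' column is all zero.
#'
#' @return An `esv_coefficients` object (11 x 6 numeric matrix with
#'   attribute `E_a`).
#' @export
shanxi_esv_coefficients <- function() {
  f <- system.file("extdata", "esv_coefficients_shanxi.csv",
                   package = "esbundles", mustWork = TRUE)
  read_esv_coefficients(f, E_a = 1031.93)
}

#' Shanxi land-use areas, 1980 and 2020
#'
#' Published per-class areas (hm2) of the six land types for the two
#' observed benchmark dates.
#'
#' @return Data frame with columns `class`, `area_1980`, `area_2020`.
#' @export
shanxi_landuse_areas <- function() {
  f <- system.file("extdata", "landuse_areas_shanxi.csv",
                   package = "esbundles", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Published scenario edit sets
#'
#' The multiplicative transfer-probability edits that turn the NDS matrix
#' into the FPS and AEDS matrices: FPS reduces arable-to-construction
#' conversion by 70% and raises construction-to-arable and
#' unused-to-arable conversion by 30% and 50%; AEDS raises forest/grass
#' to construction by 30%, cuts construction to arable/forest/grass/water
#' by 40% and raises unused-to-construction by 50%.
#'
#' @param scenario "FPS" or "AEDS".
#' @return Data frame of [scenario_edit()] rows (`from`, `to`, `multiplier`).
#' @export
shanxi_scenario_edits <- function(scenario = c("FPS", "AEDS")) {
  scenario <- match.arg(scenario)
  if (scenario == "FPS") {
    rbind(
      scenario_edit("AL", "CL", 0.3),
      scenario_edit("CL", "AL", 1.3),
      scenario_edit("UL", "AL", 1.5))
  } else {
    rbind(
      scenario_edit("FO", "CL", 1.3),
      scenario_edit("GL", "CL", 1.3),
      scenario_edit("CL", "AL", 0.6),
      scenario_edit("CL", "FO", 0.6),
      scenario_edit("CL", "GL", 0.6),
      scenario_edit("CL", "WA", 0.6),
      scenario_edit("UL", "CL", 1.5))
  }
}
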