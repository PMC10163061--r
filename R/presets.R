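# Published coefficient presets: the pooled all-region growth models, the
# per-region exponent coefficients with their fitted-vs-calculated
# comparison, and the region driver links back-solved from those pairs.

#' Pooled all-region growth model presets
#'
#' The six relative logistic growth models fitted across all study regions:
#' plant height, leaf area index and dry matter, each under both drivers
#' (relative cumulative GDD and relative cumulative reference
#' evapotranspiration). Coefficients are stored exactly as published, at
#' their printed precision; nothing is re-fitted at load time.
#'
#' @return A tibble with columns `index`, `driver`, `intercept`, `slope`,
#'   `curvature` (NA for the linear forms).
#' @seealso [cotton_model()] to get one preset as a usable model object.
#' @examples
#' cotton_growth_presets()
#' @export
cotton_growth_presets <- function() {
  tibble::tribble(
    ~index, ~driver, ~intercept, ~slope, ~curvature,
    "H",   "cgdd", 2.82,  -5.424,  NA,
    "H",   "ceto", 3.212, -6.091,  NA,
    "LAI", "cgdd", 4.553, -16.03,  10.09,
    "LAI", "ceto", 5.024, -15.66,  9.5,
    "D",   "cgdd", 2.877, -5.764,  NA,
    "D",   "ceto", 3.206, -6.163,  NA
  )
}

#' Retrieve a preset growth model
#'
#' @param index `"H"`, `"LAI"` or `"D"`.
#' @param driver `"cgdd"` or `"ceto"`.
#' @param region A region name from [cotton_region_params()], or `"Total"`
#'   (default) for the pooled all-region model.
#' @return A [logistic_growth()] object.
#' @examples
#' cotton_model("LAI", "cgdd")
#' cotton_model("H", "ceto", region = "Korla")
#' @export
cotton_model <- function(index = c("H", "LAI", "D"),
                         driver = c("cgdd", "ceto"),
                         region = "Total") {
  index <- match.arg(index)
  driver <- match.arg(driver)
  tab <- cotton_region_params()
  row <- tab[tab$index == index & tab$region == region, ]
  if (nrow(row) != 1) {
    abort(paste0("No preset for index ", index, " in region ", region, "."))
  }
  if (driver == "cgdd") {
    cf <- c(row$a, row$b, row$c)
  } else {
    cf <- c(row$d_fit, row$e_fit, row$f_fit)
  }
  curv <- if (index == "LAI") cf[3] else NULL
  logistic_growth(cf[1], cf[2], curvature = curv, driver = driver, index = index)
}

#' Per-region growth model coefficients and their cross-driver comparison
#'
#' The published per-region exponent coefficients: the CGDD-based
#' coefficients (`a`, `b`, `c`), the directly fitted CETo-based coefficients
#' (`d_fit`, `e_fit`, `f_fit`), the CETo-based coefficients calculated
#' algebraically through the linear driver link (`d_cal`, `e_cal`, `f_cal`),
#' and the published relative deviations between the two (`re_d`, `re_e`,
#' `re_f`). Quadratic columns are `NA` for the height and dry-matter rows.
#' The `"Total"` rows are the pooled models of [cotton_growth_presets()].
#'
#' @return A tibble with one row per index/region combination.
#' @examples
#' dplyr::filter(cotton_region_params(), region == "Total")
#' @export
cotton_region_params <- function() {
  tibble::tribble(
    ~index, ~region, ~a, ~b, ~c,
    ~d_fit, ~e_fit, ~f_fit, ~d_cal, ~e_cal, ~f_cal, ~re_d, ~re_e, ~re_f,
    "H", "Korla",    3.190, -5.969, NA, 3.525, -6.841, NA, 3.548, -6.399, NA, 0.0065, 0.0646, NA,
    "H", "Akesu",    2.960, -5.376, NA, 2.980, -5.184, NA, 3.124, -5.418, NA, 0.0485, 0.0451, NA,
    "H", "Shihezi",  3.199, -5.425, NA, 3.676, -5.296, NA, 3.463, -5.705, NA, 0.0578, 0.0773, NA,
    "H", "Changji",  2.461, -6.571, NA, 2.769, -6.352, NA, 2.977, -6.804, NA, 0.0751, 0.0711, NA,
    "H", "Urumqi",   3.244, -7.648, NA, 4.001, -8.201, NA, 3.979, -8.304, NA, 0.0054, 0.0126, NA,
    "H", "Total",    2.820, -5.424, NA, 3.212, -6.091, NA, 3.149, -5.731, NA, 0.0196, 0.0592, NA,
    "LAI", "Korla",   2.266, 0.899, -10.490, 1.985, 2.491, -12.430, 2.174, 2.312, -11.246, 0.0954, 0.0718, 0.0953,
    "LAI", "Akesu",   5.415, -19.380, 12.490, 5.502, -19.075, 12.629, 6.020, -20.301, 12.587, 0.0941, 0.0643, 0.0033,
    "LAI", "Shihezi", 2.599, -5.198, -2.850, 2.545, -5.928, -2.685, 2.846, -5.174, -2.997, 0.1181, 0.1272, 0.1163,
    "LAI", "Changji", 2.274, 5.934, -38.620, 1.798, 10.997, -35.790, 1.570, 12.424, -39.988, 0.1269, 0.1298, 0.1173,
    "LAI", "Karamay", 2.844, -10.850, 4.294, 3.122, -10.480, 4.320, 2.979, -9.817, 3.848, 0.0460, 0.0632, 0.1093,
    "LAI", "Liaoning", 4.018, -13.660, 6.960, 5.414, -18.220, 9.050, 5.505, -17.038, 7.854, 0.0167, 0.0649, 0.1322,
    "LAI", "Hubei",   2.462, -8.495, 6.180, 2.281, -7.467, 5.350, 2.597, -8.436, 6.000, 0.1381, 0.1298, 0.1215,
    "LAI", "He'nan",  5.490, -20.690, 13.830, 5.839, -19.850, 12.361, 6.517, -22.240, 13.968, 0.1161, 0.1204, 0.1300,
    "LAI", "Hebei",   7.650, -28.670, 20.850, 13.511, -40.650, 21.870, 15.910, -47.635, 25.551, 0.1776, 0.1718, 0.1683,
    "LAI", "Total",   4.553, -16.03, 10.09, 5.024, -15.66, 9.500, 5.563, -18.230, 11.263, 0.1072, 0.1641, 0.1856,
    "D", "Korla",    4.452, -7.963, NA, 5.319, -9.103, NA, 4.930, -8.537, NA, 0.0732, 0.0622, NA,
    "D", "Akesu",    2.673, -5.846, NA, 2.983, -5.655, NA, 2.852, -5.891, NA, 0.0440, 0.0418, NA,
    "D", "Shihezi",  2.557, -5.557, NA, 2.990, -6.246, NA, 2.828, -5.844, NA, 0.0542, 0.0644, NA,
    "D", "Liaoning", 2.352, -6.638, NA, 3.250, -8.025, NA, 3.038, -7.490, NA, 0.0651, 0.0666, NA,
    "D", "Hubei",    4.693, -9.715, NA, 4.771, -9.564, NA, 4.846, -9.432, NA, 0.0157, 0.0138, NA,
    "D", "He'nan",   5.942, -10.400, NA, 5.978, -9.726, NA, 6.442, -10.504, NA, 0.0776, 0.0800, NA,
    "D", "Total",    2.877, -5.764, NA, 3.206, -6.163, NA, 3.227, -6.090, NA, 0.0065, 0.0119, NA
  )
}

#' Per-region driver links back-solved from published coefficient pairs
#'
#' The linear map `r_ceto = m * r_cgdd + n` for each region, recovered
#' algebraically from that region's published CGDD-based coefficients and
#' link-calculated CETo-based coefficients (`d_cal`/`e_cal`/`f_cal`). The
#' per-region links themselves were not published; these are derived, and
#' the `source_index` column records which index row each was solved from
#' (height where available, otherwise dry matter, otherwise leaf area).
#'
#' @return A tibble with columns `region`, `m`, `n`, `source_index`,
#'   `derivation`.
#' @examples
#' region_links()
#' @export
region_links <- function() {
  tab <- cotton_region_params()
  preference <- c("H", "D", "LAI")
  purrr::map_dfr(unique(tab$region), function(reg) {
    rows <- tab[tab$region == reg, ]
    idx <- preference[preference %in% rows$index][1]
    row <- rows[rows$index == idx, ]
    link <- if (idx == "LAI") {
      recover_link_quadratic(row$a, row$b, row$c, row$d_cal, row$e_cal, row$f_cal)
    } else {
      recover_link_linear(row$a, row$b, row$d_cal, row$e_cal)
    }
    tibble::tibble(
      region = reg, m = link$m, n = link$n,
      source_index = idx, derivation = "back-solved"
    )
  })
}
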