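#' Path to a bundled example data file
#'
#' The package ships the published summary tables of a red-vinasse
#' blue round scad storage study as plain CSV: per-temperature TBARS
#' regression constants (`tbars_regressions.csv`), the predicted-versus-
#' actual shelf-life comparison (`shelf_life_validation.csv`), and the
#' fatty-acid composition tables at 4/25/37 degC (`pufa_4C.csv`,
#' `pufa_25C.csv`, `pufa_37C.csv`).
#'
#' @param file File name within `extdata`; with no argument, lists the
#'   available files.
#' @return Full path (or a character vector of file names).
#' @export
shelfkin_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "shelfkin")))
  path <- system.file("extdata", file, package = "shelfkin")
  if (path == "") stop("no bundled file named '", file, "'", call. = FALSE)
  path
}

#' Bundled per-temperature TBARS regression constants
#'
#' The published linear (zero-order) regression constants of the TBARS
#' time courses for both groups at 277.15/298.15/310.15 K: slope `k`
#' (mg MDA/kg per hour), `intercept` (time-zero TBARS, mg MDA/kg) and the
#' published R^2.
#'
#' @return Data frame with columns `group`, `temperature_K`, `k`,
#'   `intercept`, `r_squared`.
#' @export
tbars_regressions <- function() {
  utils::read.csv(shelfkin_example("tbars_regressions.csv"),
                  stringsAsFactors = FALSE)
}

#' Bundled predicted-versus-actual shelf-life table
#'
#' @return Data frame with columns `group`, `temperature_K`, `actual`,
#'   `actual_unit`, `predicted`, `predicted_unit` (units `h` or `d`).
#' @export
shelf_life_validation <- function() {
  utils::read.csv(shelfkin_example("shelf_life_validation.csv"),
                  stringsAsFactors = FALSE)
}

#' Bundled fatty-acid profiles for one storage temperature
#'
#' @param temperature_C One of 4, 25, 37.
#' @return List of [fa_profile()] objects (see [read_fa_table()]).
#' @export
pufa_profiles <- function(temperature_C = c(4, 25, 37)) {
  temperature_C <- match.arg(as.character(temperature_C[1]),
                             c("4", "25", "37"))
  read_fa_table(shelfkin_example(sprintf("pufa_%sC.csv", temperature_C)))
}

#' Design and response blocks for the PUFA storage PLS model
#'
#' Builds the two-block design used to relate storage conditions to PUFA
#' composition: rows are the unique (temperature, time) storage
#' conditions of the three bundled fatty-acid tables, with the three
#' identical time-zero conditions collapsed to a single baseline row
#' (14 rows in all). The X block holds 17 zero/one condition indicators
#' (3 temperatures + 14 storage times; the baseline row carries no
#' temperature indicator) plus two continuous quality indices computed
#' from the printed class totals — PUFA/SFA and SFA+MUFA — averaged over
#' the two groups. The Y block holds the 11 per-acid percentages for each
#' group (22 columns, prefixed `EG_`/`CG_`).
#'
#' @return A list with matrices `X` (14 x 19) and `Y` (14 x 22) and a
#'   `conditions` data frame (temperature_K, time_h per row).
#' @seealso [fit_pls2()], [correlation_loadings()]
#' @export
pufa_design <- function() {
  profiles <- c(pufa_profiles(4), pufa_profiles(25), pufa_profiles(37))
  key <- vapply(profiles, function(p)
    sprintf("%.2f|%g", p$temperature, p$time), character(1))
  key[vapply(profiles, function(p) p$time == 0, logical(1))] <- "baseline|0"

  conds <- unique(data.frame(
    key = key,
    temperature_K = vapply(profiles, `[[`, numeric(1), "temperature"),
    time_h = vapply(profiles, `[[`, numeric(1), "time")))
  conds$temperature_K[conds$key == "baseline|0"] <- NA
  conds <- conds[!duplicated(conds$key), ]
  conds <- conds[order(conds$time_h, conds$temperature_K), ]

  temps <- c(277.15, 298.15, 310.15)
  times <- sort(unique(conds$time_h))
  X <- matrix(0, nrow(conds), length(temps) + length(times) + 2,
              dimnames = list(conds$key,
                              c(paste0("T", temps), paste0("t", times),
                                "PUFA_SFA", "SFA_MUFA")))
  Y <- matrix(NA_real_, nrow(conds), 22)
  acid_codes <- setdiff(names(profiles[[1]]$composition),
                        c("PUFA", "SFA", "MUFA"))
  colnames(Y) <- c(paste0("EG_", acid_codes), paste0("CG_", acid_codes))
  rownames(Y) <- conds$key

  for (i in seq_len(nrow(conds))) {
    k <- conds$key[i]
    members <- profiles[key == k]
    if (!is.na(conds$temperature_K[i]))
      X[i, paste0("T", conds$temperature_K[i])] <- 1
    X[i, paste0("t", conds$time_h[i])] <- 1
    ratios <- vapply(members, function(p) {
      pc <- p$printed_classes
      c(pc[["PUFA"]] / pc[["SFA"]], pc[["SFA"]] + pc[["MUFA"]])
    }, numeric(2))
    X[i, "PUFA_SFA"] <- mean(ratios[1, ])
    X[i, "SFA_MUFA"] <- mean(ratios[2, ])
    for (g in c("EG", "CG")) {
      gp <- members[vapply(members, function(p) p$group == g, logical(1))]
      # baseline row merges three identical time-zero profiles per group
      comp <- gp[[1]]$composition[acid_codes]
      Y[i, paste0(g, "_", acid_codes)] <- comp
    }
  }
  list(X = X, Y = Y,
       conditions = conds[, c("temperature_K", "time_h")])
}
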