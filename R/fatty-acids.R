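#' Parse a shorthand fatty-acid code
#'
#' Decodes the lipid shorthand `C<chain>:<double bonds>[n-<series>][c|t]`,
#' e.g. `"C22:6n-3"` (DHA), `"C16:0"` (palmitic acid), `"C18:2n-6c"`
#' (linoleic acid, cis). The saturation class follows from the number of
#' double bonds: 0 = SFA, 1 = MUFA, >= 2 = PUFA. A trailing `c`/`t` is
#' geometry (cis/trans), not part of the omega series; codes without an
#' `n-` suffix have no omega series.
#'
#' @param code Fatty-acid shorthand string.
#' @return An object of class `fatty_acid` with fields `code`,
#'   `chain_length`, `double_bonds`, `omega_series` (`"n-3"`, `"n-6"`,
#'   `"n-9"` or `"none"`), `geometry` (`"cis"`, `"trans"` or
#'   `"unspecified"`) and `fa_class` (`"SFA"`, `"MUFA"`, `"PUFA"`).
#' @examples
#' parse_fa_code("C22:6n-3")$fa_class   # "PUFA"
#' parse_fa_code("C18:1n-9c")$geometry  # "cis"
#' @export
parse_fa_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  m <- regmatches(code, regexec("^C([0-9]+):([0-9]+)(n-([0-9]+))?([ct])?$", code))[[1]]
  if (length(m) == 0)
    stop("malformed fatty-acid code: '", code, "'", call. = FALSE)
  chain <- as.integer(m[2])
  db <- as.integer(m[3])
  if (chain < 4)
    stop("implausible chain length in code '", code, "'", call. = FALSE)
  series <- if (nzchar(m[4])) paste0("n-", m[5]) else "none"
  geometry <- switch(m[6], c = "cis", t = "trans", "unspecified")
  fa_class <- if (db == 0) "SFA" else if (db == 1) "MUFA" else "PUFA"
  structure(list(code = code, chain_length = chain, double_bonds = db,
                 omega_series = series, geometry = geometry,
                 fa_class = fa_class),
            class = "fatty_acid")
}

#' Format a parsed fatty acid back to its shorthand code
#'
#' Inverse of [parse_fa_code()]: `format_fa_code(parse_fa_code(x)) == x`
#' for every valid shorthand.
#'
#' @param fa A `fatty_acid` object.
#' @return The shorthand string.
#' @export
format_fa_code <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  paste0("C", fa$chain_length, ":", fa$double_bonds,
         if (fa$omega_series != "none") fa$omega_series else "",
         switch(fa$geometry, cis = "c", trans = "t", ""))
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat(sprintf("<fatty_acid> %s: C%d, %d double bond(s), %s, %s, %s\n",
              x$code, x$chain_length, x$double_bonds, x$omega_series,
              x$geometry, x$fa_class))
  invisible(x)
}

#' Fatty-acid composition profile of one sample
#'
#' Relative percentages (of total fatty acids) keyed by shorthand code for
#' one (group, temperature, time) sample. When the source table also
#' prints its own PUFA/SFA/MUFA class totals, they are carried in
#' `printed_classes` and compared (not enforced) against the computed
#' totals by [class_totals()].
#'
#' @param group Group label.
#' @param temperature Storage temperature in kelvin.
#' @param time Sampling time in hours.
#' @param composition Named numeric vector, code -> percent; all >= 0 and
#'   summing to at most 100 (+0.5 tolerance for rounded tables).
#' @param printed_classes Optional named numeric vector with any of
#'   `PUFA`, `SFA`, `MUFA` totals as printed in the source table.
#' @return An object of class `fa_profile`.
#' @export
fa_profile <- function(group, temperature, time, composition,
                       printed_classes = NULL) {
  stopifnot(is.numeric(composition))
  if (length(composition) > 0 &&
      (is.null(names(composition)) || any(!nzchar(names(composition)))))
    stop("'composition' must be a named vector (code -> percent)", call. = FALSE)
  if (any(composition < 0))
    stop("percentages must be >= 0", call. = FALSE)
  if (sum(composition) > 100 + 0.5)
    stop("composition sums to more than 100% (", round(sum(composition), 2),
         ")", call. = FALSE)
  structure(list(group = group, temperature = temperature, time = time,
                 composition = composition, printed_classes = printed_classes),
            class = "fa_profile")
}

#' @export
print.fa_profile <- function(x, ...) {
  cat(sprintf("<fa_profile> %s at %.2f K, t = %g h: %d acids, total %.2f%%\n",
              x$group, x$temperature, x$time, length(x$composition),
              sum(x$composition)))
  invisible(x)
}

#' Saturation-class totals and nutrition indices of a profile
#'
#' Partitions the listed acids into SFA/MUFA/PUFA by parsing each code,
#' sums the class percentages, and computes the two composite indices of
#' meat-lipid quality: PUFA/SFA (nutritional value, higher is better) and
#' 100 - PUFA% (= SFA + MUFA share when the listing is exhaustive; a
#' tenderness/flavor proxy).
#'
#' If the profile carries table-printed class totals, the absolute
#' computed-minus-printed differences are reported in
#' `printed_discrepancy` — a value above 0.02 (two-decimal rounding slack)
#' flags a data-quality issue but is not an error.
#'
#' @param profile An [fa_profile()].
#' @return An object of class `class_summary` with `pufa_pct`, `sfa_pct`,
#'   `mufa_pct`, `pufa_sfa_ratio` (NA when sfa_pct is 0),
#'   `one_minus_pufa_pct` and (possibly NULL) `printed_discrepancy`.
#' @examples
#' p <- fa_profile("EG", 277.15, 0,
#'                 c("C16:0" = 30, "C18:1n-9c" = 20, "C22:6n-3" = 50))
#' class_totals(p)
#' @export
class_totals <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  comp <- profile$composition
  cls <- vapply(names(comp), function(code) parse_fa_code(code)$fa_class,
                character(1))
  tot <- c(PUFA = sum(comp[cls == "PUFA"]),
           SFA = sum(comp[cls == "SFA"]),
           MUFA = sum(comp[cls == "MUFA"]))
  ratio <- if (tot[["SFA"]] > 0) tot[["PUFA"]] / tot[["SFA"]] else NA_real_
  printed_disc <- NULL
  if (!is.null(profile$printed_classes)) {
    pc <- profile$printed_classes
    shared <- intersect(names(pc), names(tot))
    # compare only classes whose members are actually listed in the profile
    shared <- shared[tot[shared] > 0]
    if (length(shared))
      printed_disc <- abs(tot[shared] - pc[shared])
  }
  structure(list(pufa_pct = tot[["PUFA"]], sfa_pct = tot[["SFA"]],
                 mufa_pct = tot[["MUFA"]],
                 pufa_sfa_ratio = ratio,
                 one_minus_pufa_pct = 100 - tot[["PUFA"]],
                 printed_classes = profile$printed_classes,
                 printed_discrepancy = printed_disc),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("<class_summary> PUFA %.2f%%, SFA %.2f%%, MUFA %.2f%%\n",
              x$pufa_pct, x$sfa_pct, x$mufa_pct))
  cat(sprintf("  PUFA/SFA = %s, 100 - PUFA%% = %.2f\n",
              ifelse(is.na(x$pufa_sfa_ratio), "NA",
                     sprintf("%.3f", x$pufa_sfa_ratio)),
              x$one_minus_pufa_pct))
  if (!is.null(x$printed_discrepancy) && any(x$printed_discrepancy > 0.02))
    cat("  note: computed totals differ from printed totals by more than 0.02\n")
  invisible(x)
}

#' Per-acid drift across a storage time course
#'
#' Extracts one acid's relative percentage from a time-ordered list of
#' profiles and reports the series together with its net change
#' (last minus first).
#'
#' @param profiles List of [fa_profile()] objects sharing a time course.
#' @param code Fatty-acid shorthand present in every profile.
#' @return A list with `series` (data frame `time`, `percent`, sorted by
#'   time) and `net_change`.
#' @examples
#' p0 <- fa_profile("EG", 277.15, 0,   c("C22:6n-3" = 33.26))
#' p9 <- fa_profile("EG", 277.15, 216, c("C22:6n-3" = 31.69))
#' profile_drift(list(p0, p9), "C22:6n-3")$net_change  # -1.57
#' @export
profile_drift <- function(profiles, code) {
  if (length(profiles) < 2)
    stop("need at least 2 profiles to assess drift", call. = FALSE)
  for (p in profiles) {
    stopifnot(inherits(p, "fa_profile"))
    if (!code %in% names(p$composition))
      stop("code '", code, "' absent from profile at t = ", p$time, " h",
           call. = FALSE)
  }
  times <- vapply(profiles, `[[`, numeric(1), "time")
  pct <- vapply(profiles, function(p) p$composition[[code]], numeric(1))
  ord <- order(times)
  series <- data.frame(time = times[ord], percent = pct[ord])
  list(series = series,
       net_change = series$percent[nrow(series)] - series$percent[1])
}
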