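# most-abundant-isotope masses (Da)
monoisotopic_table <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  Na = 22.9897692809,
  S = 31.97207069,
  P = 30.97376151,
  K = 38.9637064864,
  Cl = 34.968852682,
  F = 18.9984031627
)

PROTON_MASS <- 1.00727646677
ELECTRON_MASS <- 0.00054857990907

#' Parse a Hill-style molecular formula
#'
#' Accepts element symbols followed by optional multi-digit counts
#' (`"C18H35NO2"`, `"H2O"`). Supported elements are those with an entry in
#' the monoisotopic table (C, H, N, O, Na, S, P, K, Cl, F).
#'
#' @param text Formula string.
#' @return A named integer vector of element counts (class `mol_formula`).
#' @examples
#' parse_formula("C18H35NO2")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("\\s", "", text)
  if (!nzchar(txt)) stop("empty formula", call. = FALSE)
  counts <- integer(0)
  pos <- 1L
  while (pos <= nchar(txt)) {
    rest <- substr(txt, pos, nchar(txt))
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) {
      stop("malformed formula at position ", pos, ": '",
           substr(txt, pos, pos), "'", call. = FALSE)
    }
    el <- m[2]
    if (!el %in% names(monoisotopic_table)) {
      # a two-letter guess may hide a valid one-letter element (e.g. "NO")
      el1 <- substr(el, 1, 1)
      if (nchar(el) == 2L && el1 %in% names(monoisotopic_table)) {
        el <- el1
        m[3] <- ""
        m[1] <- el1
      } else {
        stop("unknown element '", el, "' at position ", pos, call. = FALSE)
      }
    }
    cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + cnt
    pos <- pos + nchar(m[1])
  }
  if (sum(counts) == 0L) stop("formula has no atoms", call. = FALSE)
  structure(counts, class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  els <- names(x)
  # Hill order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    paste0(e, if (x[[e]] == 1L) "" else x[[e]])
  }, character(1)), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope masses (C = 12 exactly,
#' H = 1.0078250319, N = 14.0030740052, O = 15.9949146221, ...).
#'
#' @param f A [parse_formula()] object or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2")        # 2.015650
#' monoisotopic_mass("C18H35NO2") # 297.266779
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "mol_formula"))
  sum(monoisotopic_table[names(f)] * as.integer(f))
}

#' Theoretical adduct m/z
#'
#' Computes the `[M+H]+` or `[M+Na]+` m/z of a neutral formula. By default
#' the neutral-atom convention is used (add the H-atom or Na-atom mass),
#' which matches common printed tables to four decimals; setting
#' `electron_correction = TRUE` adds the cation mass instead (atom minus
#' one electron), the physically exact convention for singly charged ions.
#'
#' @param f A [parse_formula()] object or formula string.
#' @param adduct `"M+H"` or `"M+Na"`.
#' @param electron_correction Subtract the electron mass (default `FALSE`).
#' @return Theoretical m/z in Da.
#' @examples
#' adduct_mz("C18H35NO2", "M+H")  # 298.2746
#' adduct_mz("C20H39NO2", "M+H")  # 326.3059
#' @export
adduct_mz <- function(f, adduct = c("M+H", "M+Na"),
                      electron_correction = FALSE) {
  adduct <- match.arg(adduct)
  mass <- monoisotopic_mass(f)
  add <- switch(adduct,
                "M+H" = monoisotopic_table[["H"]],
                "M+Na" = monoisotopic_table[["Na"]])
  if (electron_correction) add <- add - ELECTRON_MASS
  mass + add
}

#' Signed mass error in parts per million
#'
#' `(experimental - theoretical) / theoretical * 1e6`.
#'
#' @param experimental_mz,theoretical_mz Observed and theoretical m/z.
#' @return Signed ppm error.
#' @export
ppm_error <- function(experimental_mz, theoretical_mz) {
  stopifnot(all(theoretical_mz > 0))
  (experimental_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Biotransformation mass-shift hypotheses
#'
#' Monoisotopic mass deltas of common enzymatic modifications, computed
#' from the element table (hydrogenation +H2 = +2.015650, hydration
#' +H2O = +18.010565, oxidation +O = +15.994915, methylation +CH2, and
#' their reverses).
#'
#' @return A tibble: `name`, `delta_mass`.
#' @export
shift_library <- function() {
  H <- monoisotopic_table[["H"]]
  O <- monoisotopic_table[["O"]]
  C <- monoisotopic_table[["C"]]
  tibble::tibble(
    name = c("hydrogenation", "dehydrogenation", "hydration", "dehydration",
             "oxidation", "deoxygenation", "methylation", "demethylation"),
    delta_mass = c(2 * H, -2 * H, 2 * H + O, -(2 * H + O),
                   O, -O, C + 2 * H, -(C + 2 * H))
  )
}

#' Match a product/precursor mass difference to shift hypotheses
#'
#' Finds the biotransformation hypotheses whose mass delta explains
#' `product_mz - precursor_mz` within `tol_ppm` of the product mass.
#'
#' @param precursor_mz,product_mz Observed m/z of the precursor and the
#'   putative transformation product (same adduct species).
#' @param hypotheses A tibble like [shift_library()] (`name`, `delta_mass`).
#' @param tol_ppm Tolerance in ppm of the product mass (default 5).
#' @return The matching rows of `hypotheses`, with `observed_delta` and
#'   `error_ppm` columns; zero rows when nothing matches.
#' @examples
#' match_shift(326.3059, 328.3215)  # hydrogenation
#' match_shift(326.3059, 344.3164)  # hydration
#' @export
match_shift <- function(precursor_mz, product_mz,
                        hypotheses = shift_library(), tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  delta <- product_mz - precursor_mz
  err <- (delta - hypotheses$delta_mass) / product_mz * 1e6
  out <- hypotheses[abs(err) <= tol_ppm, , drop = FALSE]
  out$observed_delta <- delta
  out$error_ppm <- err[abs(err) <= tol_ppm]
  out
}

#' Annotate experimental masses against candidate formulas
#'
#' Batch helper reproducing a mass-annotation table: for each row of
#' (experimental m/z, candidate formula, adduct) computes the theoretical
#' m/z and the signed ppm error, and flags matches within `tol_ppm`.
#'
#' @param table Data frame with columns `mz` (experimental), `formula`
#'   (text) and optionally `adduct` (default `"M+H"`) plus any id columns.
#' @param tol_ppm Acceptance tolerance (default 5 ppm).
#' @param electron_correction Passed to [adduct_mz()].
#' @return The input tibble plus `mz_theoretical`, `error_ppm`, `accepted`.
#' @export
annotate_masses <- function(table, tol_ppm = 5, electron_correction = FALSE) {
  table <- tibble::as_tibble(table)
  if (!"adduct" %in% names(table)) table$adduct <- "M+H"
  table$mz_theoretical <- purrr::map2_dbl(table$formula, table$adduct,
    function(f, a) adduct_mz(f, a, electron_correction))
  table$error_ppm <- ppm_error(table$mz, table$mz_theoretical)
  table$accepted <- abs(table$error_ppm) <= tol_ppm
  table
}
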