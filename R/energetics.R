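#' @title Interaction-energy bookkeeping for A-T base pairs
#' @description Helpers that consume externally computed counterpoise-
#'   corrected interaction energies and atoms-in-molecules (AIM) bond
#'   critical point densities for Watson-Crick and Hoogsteen A-T base
#'   pairs, and reproduce the control-difference arithmetic used to bound
#'   the strength of the noncanonical CH...O hydrogen bond. No quantum
#'   chemistry is run here; the inputs are tabulated results.
#' @name energetics
NULL

HARTREE_TO_KCALMOL <- 627.509474

# reporting rounds half away from zero (1.45 -> 1.5), unlike base round()
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a table of interaction energies and AIM densities
#'
#' Delimited text with columns `system`, `e_pair`, `e_ch_to_n`,
#' `change` (optional, recomputed and cross-checked when present),
#' `e_rot90`, `rho_nh_o`, `rho_nh_n`, `rho_ch_o`. Energies in kcal/mol
#' (attraction positive), densities in atomic units. A fixture with the
#' four published A-T systems ships in
#' `system.file("extdata", "at_pair_energies.csv", package = "isoedir")`.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A data frame of energy records.
#' @export
read_energy_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  req <- c("system", "e_pair", "e_ch_to_n", "e_rot90",
           "rho_nh_o", "rho_nh_n", "rho_ch_o")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("energy table lacks column(s): ", paste(miss, collapse = ", "))
  num <- setdiff(req, "system")
  for (cn in num) {
    df[[cn]] <- as.numeric(df[[cn]])
    if (anyNA(df[[cn]])) stop("non-numeric values in column ", cn)
  }
  rho <- c("rho_nh_o", "rho_nh_n", "rho_ch_o")
  if (any(unlist(df[rho]) < 0)) stop("AIM densities must be >= 0")
  df
}

#' Counterpoise-corrected interaction energy
#'
#' `E_int = -(e_dimer - e_mon_a - e_mon_t + cp_correction)`: the dimer
#' energy minus the monomer sum, counterpoise-corrected for basis set
#' superposition error, reported with attraction positive (the convention
#' of the published table; raw quantum-chemical binding energies are
#' negative for attraction). Inputs tagged `"hartree"` are converted to
#' kcal/mol (1 hartree = 627.509474 kcal/mol).
#'
#' @param e_dimer,e_mon_a,e_mon_t Total energies of the dimer and the two
#'   monomers.
#' @param cp_correction Counterpoise correction, same units; default 0.
#' @param units `"kcal/mol"` (default) or `"hartree"`, applying to all four
#'   inputs (mixed units are not accepted — pre-convert instead).
#' @return Interaction energy in kcal/mol, positive for attraction.
#' @examples
#' interaction_energy(-13.06, 0, 0)  # 13.06 kcal/mol attraction
#' @export
interaction_energy <- function(e_dimer, e_mon_a, e_mon_t, cp_correction = 0,
                               units = c("kcal/mol", "hartree")) {
  units <- match.arg(units)
  vals <- c(e_dimer, e_mon_a, e_mon_t, cp_correction)
  if (anyNA(vals) || any(!is.finite(vals))) stop("energies must be finite")
  raw <- e_dimer - e_mon_a - e_mon_t + cp_correction
  if (units == "hartree") raw <- raw * HARTREE_TO_KCALMOL
  -raw
}

#' Interaction-energy change upon C-H to N substitution
#'
#' The substitution control replaces the adenine C2/C8-H donating the
#' CH...O bond with a nitrogen atom, abrogating that bond. The change
#' `e_ch_to_n - e_pair` is negative when the control binds more weakly,
#' and its magnitude bounds the CH...O contribution.
#'
#' @param records A data frame with columns `e_pair` and `e_ch_to_n` (e.g.
#'   from [read_energy_table()]), or a single record as a list.
#' @return Numeric vector of changes (kcal/mol).
#' @examples
#' substitution_change(data.frame(e_pair = 13.06, e_ch_to_n = 10.51))  # -2.55
#' @export
substitution_change <- function(records) {
  if (is.null(records$e_pair) || is.null(records$e_ch_to_n)) {
    stop("records must carry `e_pair` and `e_ch_to_n`")
  }
  records$e_ch_to_n - records$e_pair
}

#' Summarize substitution and rotation controls
#'
#' Reports the range of substitution-change magnitudes and the maximum
#' 90-degree-rotation control energy (the residual attraction attributable
#' to the lone CH...O bond once the canonical H-bonds are deleted), rounded
#' to one decimal for reporting (half away from zero).
#'
#' @param records A data frame of energy records (>= 1 row) with columns
#'   `e_pair`, `e_ch_to_n`, `e_rot90`.
#' @return A list: `change_min`, `change_max` (magnitudes, kcal/mol),
#'   `rot90_max`, each accompanied by a `_reported` one-decimal version,
#'   and `changes`, the per-record signed changes.
#' @export
summarize_controls <- function(records) {
  if (!NROW(records)) stop("empty record list")
  ch <- substitution_change(records)
  if (is.null(records$e_rot90)) stop("records must carry `e_rot90`")
  list(changes = ch,
       change_min = min(abs(ch)),
       change_max = max(abs(ch)),
       rot90_max = max(records$e_rot90),
       change_min_reported = round_half_up(min(abs(ch)), 1),
       change_max_reported = round_half_up(max(abs(ch)), 1),
       rot90_max_reported = round_half_up(max(records$e_rot90), 1))
}

#' Classify an H-bond from its AIM critical point density
#'
#' Electron density at a bond critical point tracks H-bond strength: the
#' canonical N-H...O / N-H...N bonds of A-T pairs fall in roughly
#' 0.025-0.043 au, while CH...O paths show much smaller but nonzero
#' density. Below a conventional existence floor the path is not counted
#' as a bond.
#'
#' @param rho Density (au), >= 0; vectorized.
#' @param canonical_min Lower edge of the canonical-strength range
#'   (default 0.025 au).
#' @param floor Existence threshold (default 0.002 au); at or below it the
#'   class is `"none"`.
#' @return Character vector in `{"canonical-strength", "weak", "none"}`.
#' @examples
#' classify_hbond(c(0.0375, 0.0047, 0))
#' @export
classify_hbond <- function(rho, canonical_min = 0.025, floor = 0.002) {
  if (any(rho < 0)) stop("densities must be >= 0")
  ifelse(rho >= canonical_min, "canonical-strength",
         ifelse(rho > floor, "weak", "none"))
}
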