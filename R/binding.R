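#' Fraction of enzyme binding sites occupied at equilibrium
#'
#' For a target free-ligand fraction `alpha1`, the free NAD(P)H concentration
#' is `alpha1 * ligand_total`, and the fraction of enzyme sites occupied
#' follows the single-site binding isotherm
#' \eqn{F = \alpha_1 L / (\alpha_1 L + K_D)}.
#'
#' @param alpha1 Free NAD(P)H fraction (0-1).
#' @param ligand_total Total NAD(P)H concentration (uM).
#' @param kd Dissociation constant K_D (uM).
#' @return Occupied-site fraction F in \[0, 1\].
#' @export
#' @examples
#' site_occupancy(0.5, 50, 25) # half-saturation: 0.5
site_occupancy <- function(alpha1, ligand_total, kd) {
  stopifnot(alpha1 >= 0, alpha1 <= 1, ligand_total >= 0, kd >= 0)
  denom <- alpha1 * ligand_total + kd
  if (denom == 0) stop("alpha1 * ligand_total + kd must be > 0", call. = FALSE)
  alpha1 * ligand_total / denom
}

#' Enzyme concentration needed for a target free-NAD(P)H fraction
#'
#' Solution design for NAD(P)H-enzyme mixtures: the bound ligand
#' `(1 - alpha1) * ligand_total` must be accommodated by `F * S` occupied
#' sites per enzyme molecule, giving
#' \eqn{[E] = (1-\alpha_1) L / (F S)} with F from [site_occupancy()].
#'
#' @inheritParams site_occupancy
#' @param sites Integer number of NAD(P)H binding sites per enzyme molecule.
#' @return Required enzyme concentration (uM).
#' @export
#' @examples
#' required_enzyme_concentration(50, 0.5, kd = 25, sites = 2) # 25 uM
required_enzyme_concentration <- function(ligand_total, alpha1, kd, sites = 1L) {
  stopifnot(alpha1 > 0, alpha1 < 1, sites >= 1, ligand_total >= 0, kd >= 0)
  f <- site_occupancy(alpha1, ligand_total, kd)
  if (f == 0) stop("target unreachable: zero site occupancy", call. = FALSE)
  (1 - alpha1) * ligand_total / (f * sites)
}

#' Free NAD(P)H fraction from total concentrations
#'
#' Forward equilibrium: solves the single-enzyme mass balance
#' \eqn{L_f + S E L_f / (L_f + K_D) = L} for the free ligand concentration
#' (closed-form positive quadratic root) and returns
#' \eqn{\alpha_1 = L_f / L}. With multiple enzymes (vector `enzyme_total` /
#' `kd` / `sites`) the competitive mass balance is solved numerically.
#'
#' @param ligand_total Total NAD(P)H (uM), > 0.
#' @param enzyme_total Total enzyme concentration(s) (uM).
#' @param kd Dissociation constant(s) (uM), recycled against `enzyme_total`.
#' @param sites Binding sites per enzyme molecule, recycled likewise.
#' @return Free fraction alpha1 in \[0, 1\]; 1 when no enzyme is present.
#' @export
#' @examples
#' predict_free_fraction(50, 25, kd = 25, sites = 2) # 0.5
predict_free_fraction <- function(ligand_total, enzyme_total, kd, sites = 1L) {
  stopifnot(ligand_total > 0, all(enzyme_total >= 0), all(kd >= 0), all(sites >= 1))
  m <- max(length(enzyme_total), length(kd), length(sites))
  enzyme_total <- rep_len(enzyme_total, m)
  kd <- rep_len(kd, m)
  sites <- rep_len(sites, m)
  if (sum(enzyme_total) == 0) return(1)
  site_tot <- sites * enzyme_total
  if (m == 1L) {
    b <- kd + site_tot - ligand_total
    lf <- if (kd == 0) {
      max(ligand_total - site_tot, 0)
    } else {
      (-b + sqrt(b^2 + 4 * kd * ligand_total)) / 2
    }
    return(lf / ligand_total)
  }
  # competitive case: occupied sites are monotone in free ligand, bisection
  balance <- function(lf) lf + sum(site_tot * lf / (lf + kd)) - ligand_total
  lf <- stats::uniroot(balance, c(0, ligand_total), tol = 1e-12)$root
  lf / ligand_total
}

#' Derived columns of an LDH/MDH mixture design
#'
#' Adds the LDH proportion `ratio = [LDH]/([LDH]+[MDH])` (also as a
#' 2-decimal display column) and the total enzyme concentration to a table
#' of mixture rows.
#'
#' @param design Data frame with numeric columns `ldh` and `mdh` (uM).
#' @return A tibble with the input columns plus `ratio` (full precision),
#'   `ratio_display` (rounded to 2 decimals), and `total` (uM).
#' @export
#' @examples
#' mixture_table(ldh_mdh_mixtures())
mixture_table <- function(design) {
  stopifnot(is.data.frame(design), all(c("ldh", "mdh") %in% names(design)))
  if (any(design$ldh < 0) || any(design$mdh < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (any(design$ldh + design$mdh == 0)) {
    stop("each mixture needs at least one nonzero enzyme", call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(design),
    ratio = .data$ldh / (.data$ldh + .data$mdh),
    ratio_display = round(.data$ratio, 2),
    total = .data$ldh + .data$mdh
  )
}

#' Placeholder NAD(P)H binding constants
#'
#' Dissociation constants and site counts for LDH, MDH and G6PDH are needed
#' to design solutions but are instrument- and buffer-dependent literature
#' values; the entries here are plausible placeholders for examples and are
#' NOT authoritative. Supply your own `kd`/`sites` for real designs.
#'
#' @return A tibble with columns `enzyme`, `kd_um`, `sites`.
#' @export
enzyme_binding_defaults <- function() {
  tibble::tibble(
    enzyme = c("LDH", "MDH", "G6PDH"),
    kd_um = c(8.8, 25, 14),
    sites = c(4L, 2L, 2L)
  )
}
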