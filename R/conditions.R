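#' Duplex reaction conditions
#'
#' Bundle of the solution parameters that enter every melting-temperature
#' calculation: limiting-strand concentration, monovalent and divalent cation
#' molarities, dNTP molarity (dNTPs chelate Mg2+ roughly stoichiometrically,
#' so the free-Mg2+ used in the salt correction is `max(mg - dntp, 0)`), and
#' the working temperature for stability queries.
#'
#' The defaults are the learning-reaction conditions used throughout the
#' package: 1.6 uM oligonucleotide, 10 mM Na+, 10 mM Mg2+, 4 mM dNTPs.
#'
#' @param strand_conc Molar concentration of the oligonucleotide strand.
#' @param na Monovalent cation molarity (mol/L).
#' @param mg Total Mg2+ molarity (mol/L).
#' @param dntp Total dNTP molarity (mol/L).
#' @param temperature Working temperature in degrees Celsius, used by
#'   stability queries (annealing, digestion stringency).
#'
#' @return An object of class `duplex_conditions` (a named list).
#' @examples
#' duplex_conditions()
#' duplex_conditions(strand_conc = 1.6e-5)
#' @export
duplex_conditions <- function(strand_conc = 1.6e-6, na = 0.010, mg = 0.010,
                              dntp = 0.004, temperature = 25) {
  vals <- c(strand_conc = strand_conc, na = na, mg = mg, dntp = dntp)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all concentrations must be finite and >= 0")
  }
  if (strand_conc <= 0) abort("`strand_conc` must be > 0")
  if (na <= 0 && max(mg - dntp, 0) <= 0) {
    abort("at least one of `na` or free Mg2+ (mg - dntp) must be > 0")
  }
  structure(
    list(strand_conc = strand_conc, na = na, mg = mg, dntp = dntp,
         temperature = temperature),
    class = "duplex_conditions"
  )
}

#' @export
print.duplex_conditions <- function(x, ...) {
  cat(sprintf(
    "<duplex_conditions> strand %.3g M | Na+ %.3g M | Mg2+ %.3g M | dNTP %.3g M | free Mg2+ %.3g M | %g C\n",
    x$strand_conc, x$na, x$mg, x$dntp, free_mg(x), x$temperature
  ))
  invisible(x)
}

#' @rdname duplex_conditions
#' @param cond A `duplex_conditions` object.
#' @export
free_mg <- function(cond) max(cond$mg - cond$dntp, 0)

#' Nearest-neighbor thermodynamic parameter set
#'
#' Unified nearest-neighbor parameters for DNA/DNA duplexes: per-dinucleotide
#' stack enthalpies (kcal/mol) and entropies (cal/mol/K) at 1 M Na+, duplex
#' initiation terms split by terminal base pair, and the symmetry entropy for
#' self-complementary duplexes. The table identity travels with every result
#' so runs are reproducible bit-for-bit.
#'
#' @return An object of class `nn_params`: a list with elements `name`,
#'   `dh` and `ds` (length-16 vectors named by 5'->3' dinucleotide),
#'   `init_at`/`init_gc` (c(dh, ds) per terminal A.T or G.C pair) and
#'   `sym_ds` (self-complementarity entropy, cal/mol/K).
#' @examples
#' nn_params()$dh[["CG"]]
#' @export
nn_params <- function() {
  dh <- c(AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
          TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
          CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
          GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0)
  ds <- c(AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
          TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
          CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
          GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9)
  structure(
    list(name = "unified-NN-1998/Mg-corrected-2008",
         dh = dh, ds = ds,
         init_at = c(dh = 2.3, ds = 4.1),
         init_gc = c(dh = 0.1, ds = -2.8),
         sym_ds = -1.4),
    class = "nn_params"
  )
}

#' @export
print.nn_params <- function(x, ...) {
  cat(sprintf("<nn_params> %s (16 stacks, initiation by terminal pair, symmetry dS %.1f)\n",
              x$name, x$sym_ds))
  invisible(x)
}
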