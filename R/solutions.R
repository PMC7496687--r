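# Mass-action free-ion solver for pipette/bath recipes (the calculation a
# chelator program performs for, e.g., free Mg2+ of an ATP-containing
# pipette solution). Each (cation, ligand) pair binds 1:1 with an apparent
# association constant already corrected to the recipe's pH; proton
# competition and higher complexes are folded into the apparent constants.

#' Solution recipe (total concentrations)
#'
#' @param totals named numeric vector of total concentrations, mM; names are
#'   species (cations such as `Mg`, `Ca`; ligands such as `ATP`, `GTP`,
#'   `EGTA`, `Rhod2`).
#' @param pH solution pH (5-9); metadata for matching constants.
#' @param temperature degrees C; metadata for matching constants.
#' @return object of class `solution_recipe`.
#' @examples
#' # nominally Ca2+-free pipette solution: 5 Mg-ATP + 1 MgCl2 + 0.1 Tris-GTP
#' # + 0.1 Rhod-2, i.e. 6 mM total Mg
#' rec <- solution_recipe(c(Mg = 6, ATP = 5, GTP = 0.1, Rhod2 = 0.1))
#' free_ion(rec, ion = "Mg")
#' @export
solution_recipe <- function(totals, pH = 7.2, temperature = 22) {
  if (is.null(names(totals)) || any(!nzchar(names(totals))))
    stop("`totals` must be a named vector (species -> mM)")
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("total concentrations must be finite and >= 0")
  if (pH < 5 || pH > 9) stop("pH must lie in [5, 9]")
  structure(list(totals = totals, pH = pH, temperature = temperature),
            class = "solution_recipe")
}

#' Binding table of apparent association constants
#'
#' @param constants data.frame with columns `cation`, `ligand`, `k_app`
#'   (apparent association constant, per M, at the stated pH/temperature)
#'   and `note` (provenance).
#' @return object of class `binding_table`.
#' @export
binding_table <- function(constants) {
  need <- c("cation", "ligand", "k_app", "note")
  if (!all(need %in% names(constants)))
    stop("constants need columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(constants$k_app)) || any(constants$k_app <= 0))
    stop("all k_app must be positive and finite")
  structure(list(constants = constants), class = "binding_table")
}

#' Default apparent-constant set (pH 7.2, ~22 C, I ~0.15)
#'
#' Apparent 1:1 association constants for Mg2+/Ca2+ binding to ATP, GTP,
#' EGTA and Rhod-2, proton-corrected to pH 7.2 from critical stability
#' constants (absolute log K with the terminal-phosphate pKa2 ~6.5 for the
#' nucleotides; EGTA corrected over both amine protonations). Published
#' constant sets for these equilibria differ by tens of percent between
#' compilations and ionic-strength corrections; override with
#' [binding_table()] when a specific set must be matched.
#'
#' @return a [binding_table()].
#' @export
default_binding_table <- function() {
  binding_table(data.frame(
    cation = c("Mg", "Ca", "Mg", "Ca", "Mg", "Ca", "Mg", "Ca"),
    ligand = c("ATP", "ATP", "GTP", "GTP", "EGTA", "EGTA", "Rhod2", "Rhod2"),
    k_app = c(1.05e4, 7.8e3, 8.3e3, 6.3e3, 4.0e1, 6.0e6, 1.0e2, 1.75e6),
    note = c(
      "MgATP log K 4.10 (I 0.15, 25C) / (1 + 10^(6.51 - 7.2))",
      "CaATP log K 3.97 (I 0.15, 25C), proton-corrected at pH 7.2",
      "MgGTP log K 4.00, proton-corrected at pH 7.2",
      "CaGTP log K 3.88, proton-corrected at pH 7.2",
      "MgEGTA apparent at pH 7.2 (log K' ~1.6)",
      "CaEGTA apparent at pH 7.2 (log K' ~6.8)",
      "Mg-Rhod2: weak, nominal Kd ~10 mM",
      "Ca-Rhod2 in vitro Kd 0.57 uM"),
    stringsAsFactors = FALSE))
}

# solve the coupled 1:1 equilibria; returns free concentrations (mM) for
# every species plus the bound ledger (cation x ligand, mM)
solve_free_ions <- function(recipe, table = default_binding_table(),
                            tol = 1e-12, maxit = 1e4) {
  stopifnot(inherits(recipe, "solution_recipe"),
            inherits(table, "binding_table"))
  tab <- table$constants
  species <- names(recipe$totals)
  cations <- intersect(unique(tab$cation), species)
  ligands <- intersect(unique(tab$ligand), species)
  inert <- setdiff(species, c(cations, ligands))
  # K matrix in per-mM (constants are per-M)
  K <- matrix(0, length(cations), length(ligands),
              dimnames = list(cations, ligands))
  for (r in seq_len(nrow(tab)))
    if (tab$cation[r] %in% cations && tab$ligand[r] %in% ligands)
      K[tab$cation[r], tab$ligand[r]] <- tab$k_app[r] / 1000
  m_tot <- recipe$totals[cations]
  l_tot <- recipe$totals[ligands]
  m <- m_tot   # free cations, mM
  l_free <- function(m) l_tot / (1 + as.numeric(crossprod(K, m)))
  # Gauss-Seidel over cations, each solved exactly by uniroot on its own
  # monotone conservation equation
  residual <- function(m) {
    l <- l_free(m)
    max(abs(m * (1 + as.numeric(K %*% l)) - m_tot))
  }
  it <- 0L
  if (length(cations)) {
    repeat {
      it <- it + 1L
      for (i in seq_along(cations)) {
        f <- function(x) {
          mi <- m; mi[i] <- x
          l <- l_free(mi)
          x * (1 + sum(K[i, ] * l)) - m_tot[i]
        }
        if (m_tot[i] == 0) { m[i] <- 0; next }
        m[i] <- stats::uniroot(f, c(0, m_tot[i]),
                               tol = .Machine$double.eps * max(1, m_tot[i]),
                               maxiter = 1000)$root
      }
      if (residual(m) <= tol) break
      if (it >= maxit)
        stop(sprintf("free-ion solver did not converge in %d iterations (residual %g mM)",
                     maxit, residual(m)))
    }
  }
  l <- l_free(m)
  bound <- outer(seq_along(cations), seq_along(ligands),
                 Vectorize(function(i, j) K[i, j] * m[i] * l[j]))
  dimnames(bound) <- list(cations, ligands)
  free <- c(as.list(m), as.list(l),
            as.list(recipe$totals[inert]))
  names(free) <- c(cations, ligands, inert)
  list(free = unlist(free), bound = bound, iterations = it,
       residual = if (length(cations)) residual(m) else 0)
}

#' Free concentration of an ion in a chelator-containing solution
#'
#' Solves the coupled mass-action system (1:1 binding of each cation to
#' each ligand with apparent constants, conservation of every total) and
#' returns the free concentration of `ion`. For the standard SK-recording
#' pipette solution (6 mM total Mg against 5 mM ATP + 0.1 mM GTP + 0.1 mM
#' Rhod-2 at pH 7.2) the default table yields a free Mg2+ near the
#' conventionally reported ~1.3-1.4 mM.
#'
#' @param recipe [solution_recipe()].
#' @param table [binding_table()]; default [default_binding_table()]. Every
#'   ligand in the recipe that the table knows binds; species unknown to
#'   the table are treated as inert.
#' @param ion species name present in the recipe.
#' @param tol convergence tolerance on the mass-balance residual, mM.
#' @return free concentration, mM, with the full solver output (`free`,
#'   `bound`, `iterations`, `residual`) attached as attribute
#'   `"solution"`.
#' @export
free_ion <- function(recipe, table = default_binding_table(), ion,
                     tol = 1e-12) {
  stopifnot(inherits(recipe, "solution_recipe"))
  if (!ion %in% names(recipe$totals))
    stop("ion '", ion, "' not present in the recipe")
  sol <- solve_free_ions(recipe, table, tol = tol)
  out <- unname(sol$free[ion])
  attr(out, "solution") <- sol
  out
}
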