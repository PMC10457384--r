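#' Build a kinetic scheme
#'
#' A kinetic scheme is a continuous-time Markov chain over conformational /
#' binding states, each carrying a relative conductance level (baseline 1.0;
#' more folded or bound states sit at lower levels because the accumulation of
#' positive charge near a p-type nanowire lowers its conductance).
#'
#' Off-diagonal entries of `Q` are rate constants in 1/s, except for
#' transitions listed in `pseudo_first_order`, whose entries are second-order
#' association constants in 1/(M s); their effective first-order rate is
#' `Q[i, j] * C` at ligand concentration `C` (mol/L). The diagonal is
#' recomputed so rows sum to zero at evaluation time.
#'
#' Transitions listed in `arrhenius` (columns `from`, `to`, `Ea` in J/mol and
#' optionally `A`, the prefactor in the same units as the `Q` entry) scale
#' with temperature as `k(T) = A * exp(-Ea / (R T))`. When `A` is omitted it
#' is derived so that the `Q` entry holds at the reference temperature `t_ref`
#' (default 310.15 K, pseudo-physiological conditions).
#'
#' @param states Data frame with columns `name`, `level` (relative
#'   conductance, > 0) and optionally `meaning` (free-text annotation).
#' @param Q Square numeric rate matrix, off-diagonals >= 0; the diagonal is
#'   ignored and recomputed.
#' @param arrhenius Optional data frame (`from`, `to`, `Ea`, optional `A`)
#'   of temperature-dependent transitions. States may be given by name or
#'   1-based index.
#' @param pseudo_first_order Optional data frame (`from`, `to`, `species`)
#'   marking bimolecular association steps driven by the named ligand species.
#' @param t_ref Reference temperature (K) at which `Q` is interpreted.
#' @param id Optional identifier stored in trace metadata.
#' @return An object of class `tk_scheme`.
#' @examples
#' sc <- kinetic_scheme(
#'   states = data.frame(name = c("a", "b"), level = c(1, 0.94)),
#'   Q = matrix(c(0, 10, 10, 0), 2, 2, byrow = TRUE)
#' )
#' stationary_distribution(sc)
#' @export
kinetic_scheme <- function(states, Q, arrhenius = NULL, pseudo_first_order = NULL,
                           t_ref = 310.15, id = NULL) {
  states <- tibble::as_tibble(states)
  if (!all(c("name", "level") %in% names(states))) {
    abort("`states` must have columns `name` and `level`.")
  }
  if (!"meaning" %in% names(states)) states$meaning <- NA_character_
  n <- nrow(states)
  if (anyDuplicated(states$name)) abort("State names must be unique.")
  if (any(!is.finite(states$level)) || any(states$level <= 0)) {
    abort("State `level` values must be finite and > 0.")
  }
  Q <- as.matrix(Q)
  if (nrow(Q) != n || ncol(Q) != n) abort("`Q` must be n_states x n_states.")
  off <- Q; diag(off) <- 0
  if (any(off < 0) || any(!is.finite(off))) {
    abort("Off-diagonal entries of `Q` must be finite and >= 0.")
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(states$name, states$name)

  resolve_idx <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    i <- match(as.character(x), states$name)
    if (anyNA(i)) abort(paste0("Unknown state name(s): ",
                               paste(x[is.na(i)], collapse = ", ")))
    i
  }
  if (!is.null(arrhenius)) {
    arrhenius <- tibble::as_tibble(arrhenius)
    if (!all(c("from", "to", "Ea") %in% names(arrhenius))) {
      abort("`arrhenius` needs columns `from`, `to`, `Ea`.")
    }
    arrhenius$from <- resolve_idx(arrhenius$from)
    arrhenius$to <- resolve_idx(arrhenius$to)
    if (!"A" %in% names(arrhenius)) arrhenius$A <- NA_real_
    k_ref <- Q[cbind(arrhenius$from, arrhenius$to)]
    derive <- is.na(arrhenius$A)
    arrhenius$A[derive] <- k_ref[derive] * exp(arrhenius$Ea[derive] / (R_GAS * t_ref))
    # keep Q consistent with A at t_ref
    Q[cbind(arrhenius$from, arrhenius$to)] <-
      arrhenius$A * exp(-arrhenius$Ea / (R_GAS * t_ref))
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
  }
  if (!is.null(pseudo_first_order)) {
    pseudo_first_order <- tibble::as_tibble(pseudo_first_order)
    if (!all(c("from", "to", "species") %in% names(pseudo_first_order))) {
      abort("`pseudo_first_order` needs columns `from`, `to`, `species`.")
    }
    pseudo_first_order$from <- resolve_idx(pseudo_first_order$from)
    pseudo_first_order$to <- resolve_idx(pseudo_first_order$to)
  }
  structure(
    list(states = states, Q = Q, arrhenius = arrhenius,
         pseudo_first_order = pseudo_first_order, t_ref = t_ref,
         id = id %||% "scheme"),
    class = "tk_scheme"
  )
}

#' @export
print.tk_scheme <- function(x, ...) {
  cat("<tk_scheme '", x$id, "'> ", nrow(x$states), " states, T_ref = ",
      x$t_ref, " K\n", sep = "")
  print(x$states)
  cat("Rate matrix (1/s; pseudo-first-order entries in 1/(M s)):\n")
  print(signif(x$Q, 4))
  invisible(x)
}

#' Rate matrix at a given temperature
#'
#' Applies the Arrhenius law `k(T) = A exp(-Ea / (R T))` to every transition
#' with attached activation parameters; other entries are unchanged. The
#' diagonal is recomputed so rows sum to zero.
#'
#' @param scheme A [kinetic_scheme()].
#' @param temperature Absolute temperature in K (> 0).
#' @return Rate matrix at `temperature`.
#' @export
rates_at_temperature <- function(scheme, temperature) {
  stopifnot(inherits(scheme, "tk_scheme"))
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("`temperature` must be > 0 (Kelvin).")
  }
  Q <- scheme$Q
  if (!is.null(scheme$arrhenius)) {
    a <- scheme$arrhenius
    Q[cbind(a$from, a$to)] <- a$A * exp(-a$Ea / (R_GAS * temperature))
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Effective rate matrix under experimental conditions
#'
#' Combines the Arrhenius temperature scaling with pseudo-first-order
#' association: entries flagged as bimolecular are multiplied by the
#' concentration (mol/L) of their ligand species.
#'
#' @inheritParams rates_at_temperature
#' @param concentrations Named list or vector of ligand concentrations in
#'   mol/L (or strings with units, see [parse_concentration()]). Species
#'   required by the scheme but not supplied default to 0 with a warning.
#' @return Effective first-order rate matrix (1/s).
#' @export
effective_rates <- function(scheme, temperature = NULL, concentrations = NULL) {
  stopifnot(inherits(scheme, "tk_scheme"))
  temperature <- temperature %||% scheme$t_ref
  Q <- rates_at_temperature(scheme, temperature)
  pfo <- scheme$pseudo_first_order
  if (!is.null(pfo) && nrow(pfo) > 0) {
    conc <- concentrations %||% list()
    cv <- vapply(pfo$species, function(sp) {
      if (!sp %in% names(conc)) {
        warn(paste0("No concentration supplied for species '", sp,
                    "'; assuming 0 M."))
        return(0)
      }
      parse_concentration(conc[[sp]])
    }, numeric(1))
    if (any(cv < 0)) abort("Concentrations must be >= 0.")
    Q[cbind(pfo$from, pfo$to)] <- Q[cbind(pfo$from, pfo$to)] * cv
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# states reachable from each state through positive-rate edges
reachable_ <- function(Q) {
  A <- (Q > 0); diag(A) <- TRUE
  n <- nrow(A)
  R <- A
  for (i in seq_len(ceiling(log2(max(n, 2))))) {
    R <- (R %*% R) > 0
  }
  R
}

#' Stationary distribution of a kinetic scheme
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` for the occupancy vector of the
#' continuous-time chain under the given conditions.
#'
#' @inheritParams effective_rates
#' @return Named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(scheme, temperature = NULL,
                                    concentrations = NULL) {
  Q <- if (inherits(scheme, "tk_scheme")) {
    effective_rates(scheme, temperature, concentrations)
  } else {
    as.matrix(scheme)
  }
  n <- nrow(Q)
  nm <- rownames(Q) %||% as.character(seq_len(n))
  R <- reachable_(Q)
  comm <- R & t(R)
  # closed communicating classes: no positive rate leaves the class
  classes <- unique(apply(comm, 1, which, simplify = FALSE))
  closed <- Filter(function(cl) all(Q[cl, -cl, drop = FALSE] <= 0) ||
                     length(cl) == n, classes)
  if (length(closed) == 0L) closed <- list(seq_len(n))
  if (length(closed) > 1L) {
    abort(paste0(
      "Chain is reducible with several closed classes; stationary ",
      "distribution is ambiguous. Classes: ",
      paste(vapply(closed, function(cl) paste(nm[cl], collapse = "+"),
                   character(1)), collapse = " | ")))
  }
  cl <- closed[[1]]
  Qc <- Q[cl, cl, drop = FALSE]
  diag(Qc) <- 0
  diag(Qc) <- -rowSums(Qc)
  m <- length(cl)
  pi <- numeric(n)
  if (m == 1L) {
    pi[cl] <- 1
  } else {
    # pi Q = 0 with the sum constraint replacing one redundant equation
    A <- t(Qc)
    A[m, ] <- 1
    b <- c(rep(0, m - 1), 1)
    pic <- solve(A, b)
    pic[pic < 0 & pic > -1e-12] <- 0
    pi[cl] <- pic / sum(pic)
  }
  names(pi) <- nm
  pi
}

#' Two-state binding scheme (encounter intermediate vs bound complex)
#'
#' The minimal bistate model of partner binding: the encounter-intermediate
#' state (higher current) exchanges with the fully folded bound complex
#' (lower current). Association is pseudo-first-order in the partner
#' concentration with `k_on = k_diss / kd`, so the stationary bound fraction
#' is `C / (C + kd)`.
#'
#' @param kd Dissociation constant, mol/L.
#' @param k_diss Dissociation rate constant, 1/s (inverse mean bound dwell).
#' @param levels Length-2 relative-conductance levels `(unbound, bound)`.
#' @param ea_bind,ea_diss Optional activation energies (J/mol) attached to
#'   the association / dissociation steps.
#' @param species Ligand species name used in `concentrations` maps.
#' @param t_ref Reference temperature (K).
#' @return A `tk_scheme` with states `Myc*` and `bound`.
#' @export
binding_scheme <- function(kd, k_diss, levels = c(1.0, 0.94),
                           ea_bind = NULL, ea_diss = NULL,
                           species = "partner", t_ref = 310.15) {
  stopifnot(kd > 0, k_diss > 0)
  k_on <- k_diss / kd  # 1/(M s)
  states <- tibble::tibble(
    name = c("Myc*", "bound"),
    level = levels,
    meaning = c("encounter intermediate", "fully folded binding complex")
  )
  Q <- matrix(0, 2, 2)
  Q[1, 2] <- k_on
  Q[2, 1] <- k_diss
  arr <- NULL
  if (!is.null(ea_bind) || !is.null(ea_diss)) {
    arr <- tibble::tibble(
      from = c(1L, 2L), to = c(2L, 1L),
      Ea = c(ea_bind %||% 0, ea_diss %||% 0)
    )
  }
  kinetic_scheme(states, Q, arrhenius = arr,
                 pseudo_first_order = tibble::tibble(from = 1L, to = 2L,
                                                     species = species),
                 t_ref = t_ref, id = "binding")
}

#' Apo self-folding scheme with a parallel medium-current branch
#'
#' A four-state model of the free-peptide clustered folding pulses: a linear
#' chain `0 <-> 1 <-> 2` over descending current levels plus a parallel
#' branch `0 <-> 1*` whose state shares the medium current level with state 1
#' but dwells longer. Medium-level dwell times are then a two-component
#' exponential mixture, as seen in temperature-resolved recordings.
#'
#' @param tau1 Mean dwell of state 1 (s); its exit rate is split between
#'   returning to 0 and advancing to 2.
#' @param tau1_star Mean dwell of the parallel `1*` state (s).
#' @param tau0,tau2 Mean dwells of the high- and low-current states (s).
#' @param p_star Probability that a departure from state 0 enters `1*`
#'   rather than 1.
#' @param levels Relative conductance of states `0`, `1`/`1*`, `2`.
#' @return A `tk_scheme` with states `0`, `1`, `1*`, `2`.
#' @export
apo_scheme <- function(tau1 = 1e-4, tau1_star = 5e-4, tau0 = 5e-4,
                       tau2 = 2e-4, p_star = 0.3, levels = c(1.0, 0.97, 0.94)) {
  stopifnot(tau1 > 0, tau1_star > 0, tau0 > 0, tau2 > 0,
            p_star > 0, p_star < 1)
  states <- tibble::tibble(
    name = c("0", "1", "1*", "2"),
    level = c(levels[1], levels[2], levels[2], levels[3]),
    meaning = c("disordered ensemble", "partially folded intermediate",
                "long-lived medium-level intermediate", "compact intermediate")
  )
  Q <- matrix(0, 4, 4)
  k0 <- 1 / tau0
  Q[1, 2] <- k0 * (1 - p_star)   # 0 -> 1
  Q[1, 3] <- k0 * p_star         # 0 -> 1*
  k1 <- 1 / tau1
  Q[2, 1] <- k1 / 2              # 1 -> 0
  Q[2, 4] <- k1 / 2              # 1 -> 2
  Q[3, 1] <- 1 / tau1_star       # 1* -> 0
  Q[4, 2] <- 1 / tau2            # 2 -> 1
  kinetic_scheme(states, Q, id = "apo")
}

#' Competition scheme between a partner and an inhibitor
#'
#' Builds a scheme in which the partner-bound and inhibitor-bound complexes
#' are mutually exclusive. Two topologies are available:
#'
#' * `"distinct"` (default): each ligand recruits its own encounter
#'   intermediate (`Myc*` for the partner, `Myc*I` for the inhibitor) from
#'   the free disordered state, then folds into its complex. This mirrors
#'   the observation that different ligands imprint different intermediate
#'   ensembles.
#' * `"shared"`: a single intermediate binds either ligand directly — the
#'   textbook purely competitive mechanism, for which the apparent
#'   dissociation constant follows `kd_partner * (1 + I / kd_inhibitor)`.
#'
#' Association steps are pseudo-first-order in species `"partner"` and
#' `"inhibitor"`.
#'
#' @param kd_partner,kd_inhibitor Dissociation constants, mol/L.
#' @param k_diss_partner,k_diss_inhibitor Dissociation rates, 1/s.
#' @param k_fold,k_unfold For `"distinct"`: folding rate into each encounter
#'   intermediate per molar ligand (1/(M s)) and its decay back to the free
#'   state (1/s).
#' @param topology `"distinct"` or `"shared"`.
#' @param levels Named conductance levels; defaults keep the ordering
#'   bound < intermediates < free.
#' @return A `tk_scheme`.
#' @export
competition_scheme <- function(kd_partner, kd_inhibitor,
                               k_diss_partner = 200, k_diss_inhibitor = 200,
                               k_fold = 5e8, k_unfold = 500,
                               topology = c("distinct", "shared"),
                               levels = NULL) {
  topology <- match.arg(topology)
  stopifnot(kd_partner > 0, kd_inhibitor > 0)
  if (k_diss_partner <= 0 || k_diss_inhibitor <= 0) {
    abort("Zero dissociation rate with nonzero association is an irreversible trap.")
  }
  if (topology == "shared") {
    levels <- levels %||% c(1.0, 0.94, 0.955)
    states <- tibble::tibble(
      name = c("Myc*", "boundP", "boundI"),
      level = levels,
      meaning = c("shared encounter intermediate", "partner complex",
                  "inhibitor complex")
    )
    Q <- matrix(0, 3, 3)
    Q[1, 2] <- k_diss_partner / kd_partner
    Q[2, 1] <- k_diss_partner
    Q[1, 3] <- k_diss_inhibitor / kd_inhibitor
    Q[3, 1] <- k_diss_inhibitor
    pfo <- tibble::tibble(from = c(1L, 1L), to = c(2L, 3L),
                          species = c("partner", "inhibitor"))
    return(kinetic_scheme(states, Q, pseudo_first_order = pfo,
                          id = "competition_shared"))
  }
  levels <- levels %||% c(1.0, 0.97, 0.94, 0.96, 0.955)
  states <- tibble::tibble(
    name = c("free", "Myc*", "boundP", "Myc*I", "boundI"),
    level = levels,
    meaning = c("disordered free state", "partner encounter intermediate",
                "partner complex", "inhibitor encounter intermediate",
                "inhibitor complex")
  )
  # Folding rates into each complex are chosen so the overall free <-> bound
  # equilibrium of each branch reproduces its dissociation constant:
  # Kd_branch = (k_unfold * k_diss) / (k_fold * k_fold2).
  Q <- matrix(0, 5, 5)
  Q[1, 2] <- k_fold          # free + P -> Myc*, 1/(M s)
  Q[2, 1] <- k_unfold
  Q[2, 3] <- k_unfold * k_diss_partner / (k_fold * kd_partner)
  Q[3, 2] <- k_diss_partner
  Q[1, 4] <- k_fold          # free + I -> Myc*I
  Q[4, 1] <- k_unfold
  Q[4, 5] <- k_unfold * k_diss_inhibitor / (k_fold * kd_inhibitor)
  Q[5, 4] <- k_diss_inhibitor
  pfo <- tibble::tibble(from = c(1L, 1L), to = c(2L, 4L),
                        species = c("partner", "inhibitor"))
  kinetic_scheme(states, Q, pseudo_first_order = pfo, id = "competition")
}
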