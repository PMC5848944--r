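# Small's group-contribution method: delta = rho * sum(F_i) / M for a repeat
# unit of molar mass M (g/mol) and density rho (g/cm^3), F_i in
# (J cm^3)^(1/2)/mol, giving delta in (J/cm^3)^(1/2).

#' Molar attraction constant table
#'
#' A named set of molar attraction constants \eqn{F_i} in
#' \eqn{(J\,cm^3)^{1/2}/mol}, one per functional group, used by
#' [sum_attraction()] and [compute_delta()].
#'
#' @param entries Named numeric vector: group name to \eqn{F_i}.
#' @param source Text label recording where the constants come from.
#' @return An object of class `attraction_table`.
#' @seealso [small_attraction_table()] for the packaged constant set,
#'   [read_attraction_table()] to load one from a delimited file.
#' @examples
#' tab <- attraction_table(c(CH2 = 272, CH = 57), source = "demo")
#' sum_attraction(c(CH2 = 2, CH = 1), tab)
#' @export
attraction_table <- function(entries, source = "user-supplied") {
  if (!is.numeric(entries) || length(entries) == 0)
    stop("`entries` must be a non-empty named numeric vector")
  nm <- names(entries)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm)))
    stop("every attraction constant must carry a group name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate group names in attraction table: ", paste(dup, collapse = ", "))
  if (any(!is.finite(entries)))
    stop("attraction constants must be finite")
  structure(list(entries = entries, source = as.character(source)[1]),
            class = "attraction_table")
}

#' @export
print.attraction_table <- function(x, ...) {
  cat("Molar attraction constants (", length(x$entries), " groups)\n", sep = "")
  cat("  source:", x$source, "\n")
  print(x$entries)
  invisible(x)
}

#' Packaged molar attraction constants
#'
#' Small's constants converted to SI units, \eqn{(J\,cm^3)^{1/2}/mol}
#' (conversion factor 2.0455 from \eqn{(cal\,cm^3)^{1/2}/mol}), supplemented
#' with hydroxyl and carboxyl entries from Hoy's compilation. Group
#' decompositions and constant sets differ between tabulations; treat the
#' resulting \eqn{\Sigma F_i} as an estimate, or supply a measured
#' `attraction_sum` on the [species()] directly.
#'
#' @return An `attraction_table`.
#' @export
small_attraction_table <- function() {
  path <- system.file("extdata", "small_attraction_constants.csv",
                      package = "solrel", mustWork = TRUE)
  read_attraction_table(path, source = "Small (1953) SI conversion; OH/COOH after Hoy (1970)")
}

#' Chemical species for solubility-parameter calculation
#'
#' A polymer repeat unit, drug or solvent carrying the quantities needed by
#' Small's method. Either `group_counts` (summed against an
#' [attraction_table()]) or a directly supplied `attraction_sum` must be
#' present, unless `delta` pins the solubility parameter to a literature
#' value (used for reference species whose group decomposition is unknown).
#'
#' @param name Species label.
#' @param molar_mass Molar mass of the repeat unit, g/mol. Must be positive.
#' @param density Density, g/cm^3. Must be positive.
#' @param group_counts Optional named non-negative integer vector of
#'   functional-group counts.
#' @param attraction_sum Optional \eqn{\Sigma F_i}, \eqn{(J\,cm^3)^{1/2}/mol}.
#' @param delta Optional pinned solubility parameter \eqn{(J/cm^3)^{1/2}};
#'   when set, [compute_delta()] reports it verbatim.
#' @return An object of class `species`.
#' @examples
#' paa <- species("PAA", molar_mass = 72.06, density = 1.20,
#'                attraction_sum = 1399.83)
#' compute_delta(paa)
#' @export
species <- function(name, molar_mass, density, group_counts = NULL,
                    attraction_sum = NULL, delta = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  molar_mass <- as.numeric(molar_mass)
  density <- as.numeric(density)
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("`molar_mass` must be a positive number (g/mol)")
  if (!is.finite(density) || density <= 0)
    stop("`density` must be a positive number (g/cm^3)")
  if (!is.null(group_counts)) {
    if (!is.numeric(group_counts) || is.null(names(group_counts)))
      stop("`group_counts` must be a named numeric vector")
    if (any(group_counts < 0) || any(group_counts != round(group_counts)))
      stop("group counts must be non-negative integers")
    storage.mode(group_counts) <- "double"
  }
  if (!is.null(attraction_sum)) {
    attraction_sum <- as.numeric(attraction_sum)
    if (!is.finite(attraction_sum)) stop("`attraction_sum` must be finite")
  }
  if (!is.null(delta)) {
    delta <- as.numeric(delta)
    if (!is.finite(delta) || delta < 0)
      stop("pinned `delta` must be finite and non-negative")
  }
  if (is.null(group_counts) && is.null(attraction_sum) && is.null(delta))
    stop("species '", name,
         "' needs at least one of `group_counts`, `attraction_sum` or a pinned `delta`")
  structure(list(name = name, molar_mass = molar_mass, density = density,
                 group_counts = group_counts, attraction_sum = attraction_sum,
                 delta = delta),
            class = "species")
}

#' @export
print.species <- function(x, ...) {
  cat("Species:", x$name, "\n")
  cat(sprintf("  M = %g g/mol, rho = %g g/cm^3\n", x$molar_mass, x$density))
  if (!is.null(x$attraction_sum))
    cat(sprintf("  sum(F_i) = %g (J cm^3)^1/2 / mol\n", x$attraction_sum))
  if (!is.null(x$group_counts))
    cat("  groups:", paste(names(x$group_counts), x$group_counts,
                           sep = ":", collapse = " "), "\n")
  if (!is.null(x$delta))
    cat(sprintf("  delta pinned at %g (J/cm^3)^1/2\n", x$delta))
  invisible(x)
}

#' Sum molar attraction constants over a group decomposition
#'
#' Computes \eqn{\Sigma_i n_i F_i} for a named vector of group counts against
#' an attraction table. The empty decomposition sums to zero.
#'
#' @param group_counts Named non-negative integer vector of group counts.
#' @param table An [attraction_table()].
#' @return \eqn{\Sigma F_i} in \eqn{(J\,cm^3)^{1/2}/mol}.
#' @export
sum_attraction <- function(group_counts, table) {
  if (!inherits(table, "attraction_table"))
    stop("`table` must be an attraction_table")
  if (length(group_counts) == 0) return(0)
  if (!is.numeric(group_counts) || is.null(names(group_counts)))
    stop("`group_counts` must be a named numeric vector")
  if (any(group_counts < 0)) stop("group counts must be non-negative")
  missing <- setdiff(names(group_counts), names(table$entries))
  if (length(missing))
    stop("group(s) not in attraction table: ", paste(missing, collapse = ", "))
  sum(group_counts * table$entries[names(group_counts)])
}

#' Hildebrand solubility parameter by Small's method
#'
#' \eqn{\delta = \rho \Sigma F_i / M}. When the species carries an explicit
#' `attraction_sum` it is used directly; otherwise the sum is built from
#' `group_counts` and `table`. If both are available and disagree by more
#' than 1\% a warning is raised and the explicit sum wins. A species with a
#' pinned `delta` (a literature value) is reported verbatim.
#'
#' The result is labelled \eqn{(J/cm^3)^{1/2}}, the dimensionally consistent
#' Hildebrand unit given \eqn{F_i} in \eqn{(J\,cm^3)^{1/2}/mol}; see the
#' methods vignette for a note on unit conventions in the literature.
#'
#' @param sp A [species()].
#' @param table An [attraction_table()], required only when the species has
#'   neither `attraction_sum` nor pinned `delta`.
#' @return An object of class `solubility_result` with fields
#'   `species_name`, `delta` and `attraction_sum_used` (`NA` for pinned
#'   species).
#' @examples
#' compute_delta(species("PAA", 72.06, 1.20, attraction_sum = 1399.83))
#' @export
compute_delta <- function(sp, table = NULL) {
  if (!inherits(sp, "species")) stop("`sp` must be a species object")
  if (!is.null(sp$delta)) {
    return(new_solubility_result(sp$name, sp$delta, NA_real_))
  }
  sf <- sp$attraction_sum
  if (is.null(sf)) {
    if (is.null(table))
      stop("species '", sp$name,
           "' has no attraction_sum; an attraction table is required")
    sf <- sum_attraction(sp$group_counts, table)
  } else if (!is.null(sp$group_counts) && !is.null(table)) {
    table_sum <- sum_attraction(sp$group_counts, table)
    if (table_sum != 0 || sf != 0) {
      rel <- abs(sf - table_sum) / max(abs(sf), abs(table_sum))
      if (rel > 0.01)
        warning(sprintf(paste0("species '%s': explicit attraction_sum (%g) and ",
                               "table sum (%g) differ by %.1f%%; using the ",
                               "explicit value"),
                        sp$name, sf, table_sum, 100 * rel))
    }
  }
  delta <- sp$density * sf / sp$molar_mass
  if (delta < 0)
    stop("negative solubility parameter from attraction sum ", sf)
  new_solubility_result(sp$name, delta, sf)
}

new_solubility_result <- function(name, delta, sf) {
  structure(list(species_name = name, delta = delta, attraction_sum_used = sf),
            class = "solubility_result")
}

#' @export
print.solubility_result <- function(x, ...) {
  cat(sprintf("%s: delta = %.2f (J/cm^3)^1/2", x$species_name, x$delta))
  if (is.finite(x$attraction_sum_used))
    cat(sprintf("  [sum(F_i) = %g]", x$attraction_sum_used))
  cat("\n")
  invisible(x)
}

#' Solubility-parameter mismatch
#'
#' Absolute difference \eqn{|\delta_a - \delta_b|}, the one-dimensional
#' like-dissolves-like distance: small mismatch predicts mutual solubility.
#'
#' @param a,b Solubility parameters (numeric) or `solubility_result` objects.
#' @return Non-negative numeric mismatch.
#' @export
delta_mismatch <- function(a, b) {
  a <- as_delta(a)
  b <- as_delta(b)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("solubility parameters must be finite")
  abs(a - b)
}

as_delta <- function(x) {
  if (inherits(x, "solubility_result")) x$delta else as.numeric(x)
}

#' Rank candidates by compatibility with a reference species
#'
#' Sorts candidates by ascending solubility-parameter mismatch to the
#' reference; ties keep input order (stable sort), so equally matched
#' candidates are not reshuffled.
#'
#' @param reference A `solubility_result` (or numeric delta) for the
#'   reference species, e.g. the solvent.
#' @param candidates List of `solubility_result` objects.
#' @return A data frame with columns `species`, `delta`, `mismatch`, ordered
#'   by ascending mismatch.
#' @examples
#' water <- species("water", 18.02, 1.00, delta = 23.40)
#' paa <- species("PAA", 72.06, 1.20, attraction_sum = 1399.83)
#' salt <- species("sodium polyacrylate", 94.04, 1.32, attraction_sum = 1116.23)
#' rank_compatibility(compute_delta(water),
#'                    lapply(list(paa, salt), compute_delta))
#' @export
rank_compatibility <- function(reference, candidates) {
  ref <- as_delta(reference)
  if (length(candidates) == 0)
    return(data.frame(species = character(), delta = numeric(),
                      mismatch = numeric(), stringsAsFactors = FALSE))
  if (!all(vapply(candidates, inherits, logical(1), "solubility_result")))
    stop("`candidates` must be a list of solubility_result objects")
  out <- data.frame(
    species = vapply(candidates, `[[`, character(1), "species_name"),
    delta = vapply(candidates, `[[`, numeric(1), "delta"),
    stringsAsFactors = FALSE)
  out$mismatch <- delta_mismatch(out$delta, ref)
  out <- out[order(out$mismatch), , drop = FALSE]  # order() is stable
  rownames(out) <- NULL
  out
}
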