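# Delimited-text I/O: comma-separated, UTF-8, '#'-prefixed comment lines for
# unit metadata. Readers validate header and cell types and cite the data row
# (1-based, comments excluded) in error messages.

read_delim_table <- function(path, required_cols, numeric_cols = required_cols,
                             optional_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot read '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0) stop("empty input: '", path, "' contains no data rows")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in intersect(c(numeric_cols, optional_cols), names(df))) {
    raw <- df[[col]]
    blank <- is.na(raw) | !nzchar(raw)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(val))
    if (length(bad))
      stop(sprintf("'%s': non-numeric value \"%s\" in column '%s', row %d",
                   path, raw[bad[1]], col, bad[1]))
    if (col %in% numeric_cols && any(blank))
      stop(sprintf("'%s': missing value in column '%s', row %d",
                   path, col, which(blank)[1]))
    df[[col]] <- val
  }
  df
}

# pull "# key: value" metadata out of the comment header
read_comment_meta <- function(path, key) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[startsWith(trimws(lines), "#")]
  pat <- paste0("^#\\s*", key, "\\s*[:=]\\s*(\\S+)")
  hit <- regmatches(lines, regexec(pat, lines))
  hit <- Filter(length, hit)
  if (length(hit)) as.numeric(hit[[1]][2]) else NA_real_
}

#' Read calibration standards from a delimited file
#'
#' Expects columns `concentration` (curve units) and `absorbance`; a comment
#' line `# conc_unit_scale: <mol/L>` declares the unit scale (default
#' `1e-4` with a message when absent).
#'
#' @param path File path.
#' @return A list: `points` data frame and `conc_unit_scale`.
#' @export
read_calibration_file <- function(path) {
  df <- read_delim_table(path, c("concentration", "absorbance"))
  scale <- read_comment_meta(path, "conc_unit_scale")
  if (is.na(scale)) {
    message("no '# conc_unit_scale:' header in '", path,
            "'; assuming 1e-4 mol/L per unit")
    scale <- 1e-4
  }
  list(points = df[, c("concentration", "absorbance")],
       conc_unit_scale = scale)
}

#' Read loading experiments from a delimited file
#'
#' One experiment per row with columns `label`, `volume_l`, `c0_molL`,
#' `A_sup`, `dilution`, `particle_g`; an optional `A0` column gives a
#' measured initial absorbance instead of `c0_molL` (exactly one of the two
#' per row).
#'
#' @param path File path.
#' @param drug_molar_mass Drug molar mass, g/mol, applied to every row.
#' @return A list of [loading_experiment()] objects.
#' @export
read_loading_file <- function(path, drug_molar_mass = r6g_molar_mass) {
  df <- read_delim_table(path,
                         required_cols = c("label", "volume_l", "A_sup",
                                           "dilution", "particle_g"),
                         numeric_cols = c("volume_l", "A_sup", "dilution",
                                          "particle_g"),
                         optional_cols = c("c0_molL", "A0"))
  lapply(seq_len(nrow(df)), function(i) {
    c0 <- if ("c0_molL" %in% names(df)) df$c0_molL[i] else NA_real_
    a0 <- if ("A0" %in% names(df)) df$A0[i] else NA_real_
    if (is.na(c0) == is.na(a0))
      stop(sprintf("'%s', row %d: exactly one of c0_molL or A0 must be given",
                   path, i))
    loading_experiment(
      solution_volume_l = df$volume_l[i],
      supernatant_absorbance = df$A_sup[i],
      dilution_factor = df$dilution[i],
      particle_mass_g = df$particle_g[i],
      initial_conc_molL = if (!is.na(c0)) c0 else NULL,
      initial_absorbance = if (!is.na(a0)) a0 else NULL,
      drug_molar_mass = drug_molar_mass,
      label = df$label[i])
  })
}

#' Read a release absorbance series from a delimited file
#'
#' Expects columns `time_h` and `absorbance`. The experiment geometry
#' (volume, loaded mass, dilution) is not in the file; it is passed here.
#'
#' @param path File path.
#' @inheritParams release_series
#' @return A [release_series()].
#' @export
read_release_file <- function(path, release_volume_l, loaded_mg,
                              dilution_factor = 1,
                              drug_molar_mass = r6g_molar_mass) {
  df <- read_delim_table(path, c("time_h", "absorbance"))
  release_series(df$time_h, df$absorbance, release_volume_l, loaded_mg,
                 dilution_factor, drug_molar_mass)
}

#' Read a fraction-valued release curve from a delimited file
#'
#' Expects columns `time` and `fraction` (either \eqn{M_t/M_\infty} in
#' `[0, 1]` or cumulative percent, detected and divided by 100 when any
#' value exceeds 1.5).
#'
#' @param path File path.
#' @param time_unit `"s"` or `"h"`.
#' @return A [release_curve()].
#' @export
read_release_curve_file <- function(path, time_unit = c("s", "h")) {
  time_unit <- match.arg(time_unit)
  df <- read_delim_table(path, c("time", "fraction"))
  f <- df$fraction
  if (any(f > 1.5)) f <- f / 100
  release_curve(df$time, f, time_unit = time_unit)
}

#' Read species definitions from a delimited file
#'
#' Expects columns `name`, `molar_mass`, `density` and any of the optional
#' columns `attraction_sum`, `delta` (pinned value) and `groups`
#' (semicolon-separated `group:count` pairs, e.g. `"CH2:1;CH:1;COOH:1"`).
#'
#' @param path File path.
#' @return A named list of [species()] objects.
#' @export
read_species_file <- function(path) {
  df <- read_delim_table(path,
                         required_cols = c("name", "molar_mass", "density"),
                         numeric_cols = c("molar_mass", "density"),
                         optional_cols = c("attraction_sum", "delta"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    gc <- NULL
    if ("groups" %in% names(df) && !is.na(df$groups[i]) &&
        nzchar(df$groups[i])) {
      parts <- strsplit(strsplit(df$groups[i], ";", fixed = TRUE)[[1]],
                        ":", fixed = TRUE)
      bad <- vapply(parts, length, integer(1)) != 2
      if (any(bad))
        stop(sprintf("'%s', row %d: malformed groups field \"%s\"",
                     path, i, df$groups[i]))
      gc <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                            vapply(parts, `[`, "", 1))
    }
    num_or_null <- function(col)
      if (col %in% names(df) && !is.na(df[[col]][i])) df[[col]][i] else NULL
    species(df$name[i], df$molar_mass[i], df$density[i],
            group_counts = gc,
            attraction_sum = num_or_null("attraction_sum"),
            delta = num_or_null("delta"))
  })
  stats::setNames(out, df$name)
}

#' Read an attraction-constant table from a delimited file
#'
#' Expects columns `group` and `F` (\eqn{(J\,cm^3)^{1/2}/mol}).
#'
#' @param path File path.
#' @param source Source label; defaults to the file name.
#' @return An [attraction_table()].
#' @export
read_attraction_table <- function(path, source = basename(path)) {
  df <- read_delim_table(path, required_cols = c("group", "F"),
                         numeric_cols = "F")
  attraction_table(stats::setNames(df$F, df$group), source = source)
}

#' Write a data frame as a commented delimited file
#'
#' Comma-separated, UTF-8, with optional `#`-prefixed metadata lines before
#' the header. The package's readers ([read_calibration_file()] and
#' friends) round-trip the records.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comments Character vector of metadata lines (written as
#'   `# <line>`).
#' @return `path`, invisibly.
#' @export
write_delim_table <- function(df, path, comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
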