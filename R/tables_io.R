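# Tabular readers for RDC and relaxation-dispersion data.  Delimited
# text (TSV or CSV, chosen by extension) with a mandatory header; a
# configurable column mapping tolerates differing supplementary-table
# layouts.

.RDC_TYPES <- c("NH", "CAHA", "NC", "HNC")

# map common spellings of the four coupling types onto canonical ids
.canon_rdc_type <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  map <- c(NH = "NH", HN = "NH", DNH = "NH",
           CAHA = "CAHA", CAH = "CAHA", DCAHA = "CAHA",
           NC = "NC", NCO = "NC", DNC = "NC",
           HNC = "HNC", HNCO = "HNC", DHNC = "HNC")
  out <- unname(map[key])
  if (any(is.na(out)))
    stop("unknown RDC coupling type(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected one of N-H, CA-HA, N-C', HN-C')")
  out
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
}

#' Read a table of residual dipolar couplings
#'
#' Expects a delimited text file (tab-separated, or comma-separated for
#' a `.csv` extension) with a header.  Required columns (renameable via
#' `col_map`): `residue`, `type` (one of N-H, CA-HA, N-C', HN-C' in any
#' common spelling), `medium`, `value` (Hz), `error` (Hz).  Rows with
#' non-positive error are dropped with a warning; duplicate
#' (residue, type, medium) keys are an error.
#'
#' @param path file path.
#' @param col_map named character vector mapping required names to the
#'   file's column names, e.g. `c(residue = "resid")`.
#' @return a data frame of class `"rdc_table"` with canonical columns
#'   `residue`, `type`, `medium`, `value`, `error`.
#' @export
read_rdc_table <- function(path, col_map = NULL) {
  df <- .read_delim_auto(path)
  need <- c("residue", "type", "medium", "value", "error")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(df))
        stop("mapped column not in file: ", col_map[[nm]])
      names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  .require_cols(df, need, path)
  out <- data.frame(residue = as.integer(df$residue),
                    type = .canon_rdc_type(df$type),
                    medium = as.character(df$medium),
                    value = as.numeric(df$value),
                    error = as.numeric(df$error),
                    stringsAsFactors = FALSE)
  bad <- !is.finite(out$error) | out$error <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive error dropped")
    out <- out[!bad, ]
  }
  key <- paste(out$residue, out$type, out$medium)
  if (anyDuplicated(key))
    stop("duplicate (residue, type, medium) key: ",
         key[duplicated(key)][1])
  rownames(out) <- NULL
  class(out) <- c("rdc_table", "data.frame")
  out
}

#' Read a table of relaxation-dispersion measurements
#'
#' Required columns: `residue`, `temperature` (K), `nu_cpmg` (Hz), and
#' either `r2eff` (s^-1) with `sigma`, or `intensity` with
#' `ref_intensity` (converted via [intensities_to_r2eff()]).  Repeated
#' `nu_cpmg` points are kept as replicates, never merged.  Optional
#' columns `nucleus` and `field` are carried through.
#'
#' @param path file path.
#' @param col_map optional column mapping as in [read_rdc_table()].
#' @param t_cp constant-time CPMG period in seconds, used when
#'   converting intensities.
#' @return a data frame of class `"dispersion_table"` with columns
#'   `residue`, `temperature`, `nu_cpmg`, `r2eff`, `sigma` and a
#'   replicate index `rep`.
#' @export
read_dispersion_table <- function(path, col_map = NULL, t_cp = 0.020) {
  df <- .read_delim_auto(path)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(df))
        stop("mapped column not in file: ", col_map[[nm]])
      names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  .require_cols(df, c("residue", "temperature", "nu_cpmg"), path)
  if (any(df$nu_cpmg <= 0)) stop("nu_cpmg must be > 0")
  if (any(df$temperature < 250 | df$temperature > 330))
    stop("temperature outside the physical range 250-330 K")
  if (all(c("intensity", "ref_intensity") %in% names(df))) {
    if (any(df$intensity <= 0) || any(df$ref_intensity <= 0))
      stop("intensities must be positive")
    sig_i <- if ("sigma_intensity" %in% names(df)) df$sigma_intensity else NULL
    r2 <- intensities_to_r2eff(df$intensity, df$ref_intensity, t_cp, sig_i)
    sigma <- attr(r2, "sigma")
    if (is.null(sigma)) sigma <- NA_real_
    df$r2eff <- as.numeric(r2)
    df$sigma <- sigma
  }
  .require_cols(df, c("r2eff", "sigma"), path)
  out <- data.frame(residue = as.integer(df$residue),
                    temperature = as.numeric(df$temperature),
                    nu_cpmg = as.numeric(df$nu_cpmg),
                    r2eff = as.numeric(df$r2eff),
                    sigma = as.numeric(df$sigma),
                    stringsAsFactors = FALSE)
  if ("nucleus" %in% names(df)) out$nucleus <- df$nucleus
  if ("field" %in% names(df)) out$field <- df$field
  key <- paste(out$residue, out$temperature, out$nu_cpmg)
  out$rep <- stats::ave(seq_len(nrow(out)), key, FUN = seq_along)
  rownames(out) <- NULL
  class(out) <- c("dispersion_table", "data.frame")
  out
}

#' Write a dispersion or RDC table to delimited text
#'
#' @param x data frame.
#' @param path output path; `.csv` writes comma-separated, anything
#'   else tab-separated.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(x, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-point uncertainty of a dispersion profile from replicate spread
#'
#' For profiles acquired with repeated `nu_cpmg` points, the pooled
#' standard deviation over all replicated frequencies is assigned to
#' every point of the profile (the standard constant-time CPMG error
#' model).  Points keep their replicate identity; nothing is averaged.
#'
#' @param disp a `"dispersion_table"` data frame (one or more residues
#'   and temperatures).
#' @return the table with `sigma` filled from the replicate spread
#'   wherever replicates exist for the (residue, temperature) profile.
#' @export
sigma_from_replicates <- function(disp) {
  grp <- paste(disp$residue, disp$temperature)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- disp[idx, ]
    reps <- split(sub$r2eff, sub$nu_cpmg)
    reps <- reps[vapply(reps, length, 1L) > 1]
    if (!length(reps)) next
    v <- unlist(lapply(reps, function(x) {
      (x - mean(x))^2
    }))
    dof <- sum(vapply(reps, length, 1L) - 1L)
    disp$sigma[idx] <- sqrt(sum(v) / dof)
  }
  disp
}
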