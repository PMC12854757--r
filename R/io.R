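#' Write a trajectory in COLVAR-dialect text
#'
#' PLUMED-style whitespace text: a `#! FIELDS ...` header naming the columns
#' (`time rho_deg omega_deg bias_kBT broken`), then one row per sample.
#'
#' @param traj a `window_trajectory`.
#' @param path output path.
#' @param units a [unit_system()] (for the bias column).
#' @return `path`, invisibly.
#' @export
write_colvar <- function(traj, path, units = unit_system()) {
  stopifnot(inherits(traj, "window_trajectory"))
  bias <- if (is.null(traj$window)) rep(0, nrow(traj$samples))
          else bias_energy(traj$window, traj$samples, units)
  header <- "#! FIELDS time rho_deg omega_deg bias_kBT broken"
  meta <- c(
    if (!is.null(traj$window))
      sprintf("# window %s rho_bar_deg %.10g gamma %.10g K_kJmol %.10g",
              traj$window$window_id, traj$window$rho_bar, traj$window$gamma,
              traj$window$stiffness_k),
    sprintf("# seed %d acceptance %.6f", traj$seed_used,
            traj$acceptance_rate))
  rows <- sprintf("%.10g %.17g %.17g %.10g %d", traj$time,
                  traj$samples$roll, traj$samples$twist_excess, bias,
                  as.integer(traj$broken))
  writeLines(c(header, meta, rows), path)
  invisible(path)
}

#' Read a COLVAR-dialect trajectory file
#'
#' Parses the `#! FIELDS ...` header dialect; columns may appear in any
#' order. Required columns are roll and twist (named `rho`/`rho_deg` and
#' `omega`/`omega_deg`). Files without a FIELDS header are accepted as plain
#' headerless 3-column `(time, rho, omega)` tables. Unknown columns are kept
#' as extra columns of `$extra`.
#'
#' @param path input path.
#' @return a list of class `colvar_data`: `samples` (a [step_coords()]),
#'   `time`, `broken` (logical, `FALSE` if absent), `bias_kBT` (or `NULL`),
#'   `extra` (data.frame of unrecognized columns), `fields`.
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L) stop(sprintf("%s: empty file", path))
  fields <- NULL
  if (grepl("^#!\\s*FIELDS\\b", lines[1L])) {
    fields <- strsplit(trimws(sub("^#!\\s*FIELDS\\b", "", lines[1L])),
                       "\\s+")[[1L]]
  }
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0L) stop(sprintf("%s: no data rows", path))
  toks <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncols <- unique(lengths(toks))
  if (length(ncols) != 1L)
    stop(sprintf("%s: inconsistent column counts in data rows", path))
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = ncols, byrow = TRUE))
  bad <- which(rowSums(is.na(vals)) > 0)
  if (length(bad))
    stop(sprintf("%s: non-numeric token on line %d", path,
                 data_idx[bad[1L]]))
  if (is.null(fields)) {
    if (ncols < 3L)
      stop(sprintf(
        "%s: headerless file must have 3 columns (time, rho, omega), found %d",
        path, ncols))
    fields <- c("time", "rho_deg", "omega_deg",
                if (ncols > 3L) paste0("col", 4:ncols))
  }
  if (length(fields) != ncols)
    stop(sprintf("%s: FIELDS header names %d columns but rows have %d",
                 path, length(fields), ncols))
  colnames(vals) <- fields
  pick <- function(names) {
    hit <- intersect(names, fields)
    if (length(hit)) vals[, hit[1L]] else NULL
  }
  rho <- pick(c("rho_deg", "rho", "roll_deg", "roll"))
  omega <- pick(c("omega_deg", "omega", "twist_deg", "twist"))
  if (is.null(rho) || is.null(omega))
    stop(sprintf("%s: required columns rho and omega not found in FIELDS (%s)",
                 path, paste(fields, collapse = ", ")))
  known <- c("time", "rho_deg", "rho", "roll_deg", "roll",
             "omega_deg", "omega", "twist_deg", "twist", "bias_kBT", "broken")
  extra <- vals[, setdiff(fields, known), drop = FALSE]
  structure(
    list(samples = step_coords(0, rho, omega),
         time = if (!is.null(pick("time"))) pick("time")
                else seq_along(rho) - 1,
         broken = if (!is.null(pick("broken"))) pick("broken") != 0
                  else rep(FALSE, length(rho)),
         bias_kBT = pick("bias_kBT"),
         extra = as.data.frame(extra), fields = fields),
    class = "colvar_data"
  )
}

#' Rebuild a window trajectory from COLVAR data
#'
#' @param colvar a `colvar_data` from [read_colvar()].
#' @param window the [bias_window()] the file was sampled under (optional).
#' @return a `window_trajectory`.
#' @export
as_window_trajectory <- function(colvar, window = NULL) {
  stopifnot(inherits(colvar, "colvar_data"))
  structure(
    list(window = window, samples = colvar$samples, time = colvar$time,
         broken = colvar$broken, seed_used = NA_integer_,
         acceptance_rate = NA_real_, proposal_halfwidth = NA_real_),
    class = "window_trajectory"
  )
}

#' Write a free-energy landscape as delimited text
#'
#' Header lines carry the axes metadata and a provenance digest; data rows
#' are `rho_center omega_center deltaF_kBT masked_flag`. Values round-trip
#' bit-exactly through [read_landscape()].
#'
#' @param grid a `landscape_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(grid, path) {
  stopifnot(inherits(grid, "landscape_grid"))
  rc <- grid$binning$rho_centers
  wc <- grid$binning$omega_centers
  nr <- length(rc); nw <- length(wc)
  header <- c(
    "# dnakink landscape grid",
    sprintf("# rho_edges %s", paste(sprintf("%.17g", grid$binning$rho_edges),
                                    collapse = " ")),
    sprintf("# omega_edges %s",
            paste(sprintf("%.17g", grid$binning$omega_edges), collapse = " ")),
    sprintf("# reference %.17g %.17g", grid$reference[["rho"]],
            grid$reference[["omega"]]),
    sprintf("# converged %d iterations %d residual %.17g",
            as.integer(isTRUE(grid$converged)), grid$iterations,
            grid$residual),
    sprintf("# provenance %s", grid$provenance),
    "rho_center omega_center deltaF_kBT masked"
  )
  rows <- sprintf("%.17g %.17g %s %d",
                  rep(rc, times = nw), rep(wc, each = nr),
                  ifelse(is.na(as.vector(grid$deltaF)), "NA",
                         sprintf("%.17g", as.vector(grid$deltaF))),
                  as.integer(!as.vector(grid$mask)))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(sprintf("^# %s ", key), lines, value = TRUE)
    if (!length(ln)) stop(sprintf("%s: missing '# %s' header", path, key))
    trimws(sub(sprintf("^# %s ", key), "", ln[1L]))
  }
  rho_edges <- as.numeric(strsplit(grab("rho_edges"), "\\s+")[[1L]])
  omega_edges <- as.numeric(strsplit(grab("omega_edges"), "\\s+")[[1L]])
  binning <- binning2d(rho_edges, omega_edges)
  nr <- length(binning$rho_centers); nw <- length(binning$omega_centers)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  body <- body[-1L]  # column-name line
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) != 4L)) stop(sprintf("%s: malformed data row", path))
  m <- matrix(unlist(toks), ncol = 4L, byrow = TRUE)
  if (nrow(m) != nr * nw)
    stop(sprintf("%s: expected %d rows, found %d", path, nr * nw, nrow(m)))
  vals3 <- suppressWarnings(as.numeric(m[, 3L]))
  if (any(is.na(vals3) & m[, 3L] != "NA"))
    stop(sprintf("%s: non-numeric deltaF value", path))
  deltaF <- matrix(vals3, nr, nw)
  mask <- matrix(m[, 4L] == "0", nr, nw)
  ref <- as.numeric(strsplit(grab("reference"), "\\s+")[[1L]])
  conv <- strsplit(grab("converged"), "\\s+")[[1L]]  # "<flag> iterations <n> residual <r>"
  structure(
    list(binning = binning, deltaF = deltaF, mask = mask,
         reference = c(rho = ref[1L], omega = ref[2L]),
         f = NULL, iterations = as.integer(conv[3L]),
         converged = conv[1L] == "1", residual = as.numeric(conv[5L]),
         residual_tail = NULL, provenance = grab("provenance")),
    class = "landscape_grid"
  )
}

#' Read a base-pair-step parameter table
#'
#' Accepts two dialects: 3DNA `.par`-style whitespace tables (a header row
#' naming columns, first column a step/base-pair label, angles among the
#' columns `tilt`, `roll`, `twist`) and labeled CSV with the same column
#' names. Twist in these tables is absolute helical twist; it is converted
#' to excess twist by subtracting the configured intrinsic twist before any
#' classification.
#'
#' @param path input path.
#' @param intrinsic_twist intrinsic helical twist per step in degrees
#'   (default 34.3; a convention, flagged in output).
#' @return a data.frame of class `steppar_table` with columns `step`
#'   (dinucleotide label), `tilt`, `roll`, `twist` (absolute),
#'   `twist_excess`, plus any further numeric columns present;
#'   `intrinsic_twist` is attached as an attribute.
#' @export
read_steppar <- function(path, intrinsic_twist = 34.3) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- tryCatch({
    if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    } else {
      utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                        comment.char = "#")
    }
  }, error = function(e)
    stop(sprintf("%s: cannot parse step-parameter table (%s)", path,
                 conditionMessage(e))))
  names(df) <- tolower(names(df))
  lbl_col <- intersect(c("step", "bp_step", "base_pair", "bp", "label"),
                       names(df))
  if (!length(lbl_col)) {
    if (!is.numeric(df[[1L]])) lbl_col <- names(df)[1L]
    else stop(sprintf("%s: no step-label column found", path))
  }
  need <- c("tilt", "roll", "twist")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  for (cc in need)
    if (!is.numeric(df[[cc]]) || any(!is.finite(df[[cc]])))
      stop(sprintf("%s: column '%s' must be finite numeric", path, cc))
  step <- toupper(gsub("[^A-Za-z]", "", df[[lbl_col[1L]]]))
  out <- data.frame(step = step, tilt = df$tilt, roll = df$roll,
                    twist = df$twist,
                    twist_excess = df$twist - intrinsic_twist,
                    stringsAsFactors = FALSE)
  for (cc in intersect(c("shift", "slide", "rise"), names(df)))
    out[[cc]] <- df[[cc]]
  attr(out, "intrinsic_twist") <- intrinsic_twist
  class(out) <- c("steppar_table", "data.frame")
  out
}

#' Annotate a step-parameter table with kink calls
#'
#' Applies [classify_kink()] per step on (roll, excess twist).
#'
#' @param table a `steppar_table` from [read_steppar()].
#' @param settings a [kink_settings()].
#' @return the table with an added `kink` column (factor TB/PB/none); the
#'   thresholds are attached as attribute `settings`.
#' @export
annotate_kinks <- function(table, settings = kink_settings()) {
  stopifnot(inherits(table, "steppar_table"))
  calls <- classify_kink(
    step_coords(table$tilt, table$roll, table$twist_excess), settings)
  table$kink <- calls$kind
  attr(table, "settings") <- settings
  table
}
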