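#' Read a long-format count table
#'
#' Reads a delimited text file with one row per (individual, assessment) and
#' validates it into the canonical long format with columns `id`,
#' `age_months`, `count`, `exposure`.  Rows failing validation (non-integer
#' or negative counts, exposures below one, unparseable ages) are rejected
#' with a warning naming their line numbers and returned in the
#' `"rejected"` attribute.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(exposure = "utts")`.
#' @param sep field separator (default `","`; use `"\t"` for TSV).
#' @return Data frame with the canonical columns; attributes `rejected`
#'   (row numbers) and `n_rejected`.
#' @export
read_long_counts <- function(path, column_map = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  canonical <- c("id", "age_months", "count", "exposure")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("mapped column '", src, "' not found")
      names(df)[names(df) == src] <- canon
    }
  }
  miss <- setdiff(canonical, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[canonical]
  suppressWarnings({
    age <- as.numeric(df$age_months)
    y <- as.numeric(df$count)
    u <- as.numeric(df$exposure)
  })
  bad <- is.na(age) | is.na(y) | is.na(u) | y < 0 | y != round(y) | u < 1
  if (any(bad))
    warning(sum(bad), " row(s) failed validation and were rejected (lines ",
            paste(utils::head(which(bad) + 1L, 20L), collapse = ", "),
            if (sum(bad) > 20L) ", ..." else "", ")")
  out <- data.frame(id = df$id[!bad], age_months = age[!bad],
                    count = as.integer(y[!bad]), exposure = u[!bad])
  attr(out, "rejected") <- which(bad)
  attr(out, "n_rejected") <- sum(bad)
  out
}

.report_stamp <- function(seed = NULL) {
  list(package = "slcmcount",
       version = as.character(utils::packageVersion("slcmcount")),
       seed = seed)
}

#' Serialize results to disk
#'
#' Writes a machine-readable report: JSON for model fits, selection reports
#' and recovery studies; CSV for plain tables (bin fits, binned data).  JSON
#' numeric fields are written at full precision so a written-then-read
#' report reproduces estimates and log-likelihoods exactly.
#'
#' @param object an [slcm()] fit, [fit_bins()] table, [select_count_family()]
#'   report, [recovery_study()] result, or data frame.
#' @param path output file path (`.json` or `.csv` accordingly).
#' @param seed optional seed to record in the report stamp.
#' @return `path`, invisibly.
#' @seealso [read_slcm_report()]
#' @export
write_slcm_report <- function(object, path, seed = NULL) {
  if (inherits(object, "slcm")) {
    pm <- object$parmap
    est <- .natural_from_internal(object$theta_internal, pm,
                                  object$layout$tvals)
    rep_ <- list(
      stamp = .report_stamp(seed),
      config = list(dispersion = object$dispersion_form,
                    random = object$random,
                    re_structure = object$re_structure,
                    quad = unclass(object$quad),
                    control = unclass(object$control),
                    origin = object$origin),
      estimates = as.list(est),
      fixed = as.list(coef(object)),
      T = object$T,
      dispersion = if (inherits(object$dispersion, "dispersion_trajectory"))
        list(form = object$dispersion$form,
             coeffs = as.list(object$dispersion$coeffs))
      else list(form = "free", phi = as.list(object$phi_w)),
      loglik = object$loglik, aic = object$aic, bic = object$bic,
      n_par = object$n_par,
      se_model = if (!is.null(object$vcov)) as.list(robust_se(object, "model")),
      se_robust = if (!is.null(object$vcov)) as.list(robust_se(object, "robust")),
      identification = unclass(object$identification),
      convergence = c(list(converged = object$converged,
                           boundary_changepoint = object$boundary_changepoint),
                      object$optim),
      n_individuals = object$n_individuals, n_obs = object$n_obs,
      W = object$W, changepoint_age = object$coefficients[["changepoint"]] +
        object$origin)
    jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, matrix = "rowmajor")
  } else if (inherits(object, "family_selection")) {
    jsonlite::write_json(c(list(stamp = .report_stamp(seed)),
                           lapply(unclass(object), identity)),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  } else if (inherits(object, "recovery_study")) {
    jsonlite::write_json(c(list(stamp = .report_stamp(seed)),
                           unclass(object)),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  } else if (is.data.frame(object)) {
    utils::write.csv(object, path, row.names = FALSE)
  } else stop("no writer for objects of class ", paste(class(object),
                                                       collapse = "/"))
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path path written by [write_slcm_report()].
#' @return Parsed list with numeric fields at full precision.
#' @export
read_slcm_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
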