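# Batch metric tables and the pairwise Pearson correlation report used to
# contrast the ornamentation index with shape-confounded complexity
# measures (S/V, rugosity, fractal dimension) across a sample of shells.

metrics_columns <- c(
  "specimen_id", "S", "S_ref", "V", "Sp", "OI", "sv_ratio", "rugosity",
  "fd", "U_D", "W_H", "W_D"
)

#' Assemble a per-specimen metrics record
#'
#' One row per specimen with the canonical column set; metrics whose
#' preconditions failed are `NA`.  `OI` is stored as a dimensionless
#' fraction; report writers render percent.
#'
#' @param specimen_id Identifier.
#' @param S,S_ref Surface areas of specimen and smooth reference (mm^2).
#' @param V Enclosed volume (mm^3).
#' @param Sp Projected silhouette area (mm^2).
#' @param OI Ornamentation index (fraction).
#' @param sv_ratio Surface-to-volume ratio (mm^-1).
#' @param rugosity Dimensionless rugosity.
#' @param fd Bouligand-Minkowski fractal dimension.
#' @param U_D,W_H,W_D Caller-supplied shape ratios (umbilical
#'   diameter/diameter, width/height, width/diameter).
#' @return A one-row tibble.
#' @export
metrics_record <- function(specimen_id, S = NA_real_, S_ref = NA_real_,
                           V = NA_real_, Sp = NA_real_, OI = NA_real_,
                           sv_ratio = NA_real_, rugosity = NA_real_,
                           fd = NA_real_, U_D = NA_real_, W_H = NA_real_,
                           W_D = NA_real_) {
  tibble::tibble(
    specimen_id = as.character(specimen_id),
    S = S, S_ref = S_ref, V = V, Sp = Sp, OI = OI,
    sv_ratio = sv_ratio, rugosity = rugosity, fd = fd,
    U_D = U_D, W_H = W_H, W_D = W_D
  )
}

#' Compute every applicable metric for a specimen mesh
#'
#' Routes each metric through its precondition: volume and S/V require a
#' watertight mesh, silhouette metrics require a projection normal (given or
#' estimated), OI requires a smooth reference.  Metrics that do not apply
#' are `NA` in the returned row, with a logged reason.
#'
#' @inheritParams oi_from_meshes
#' @param fd Logical: also compute the Bouligand-Minkowski fractal dimension
#'   (slower; default `FALSE`).
#' @param spacing,radii Voxel settings for `fd = TRUE`.
#' @param shape_ratios Optional named list/vector with any of `U_D`, `W_H`,
#'   `W_D` (caller-measured shape ratios; they are not derived from the
#'   mesh).
#' @return A one-row tibble, see [metrics_record()].
#' @export
compute_all_metrics <- function(mesh, reference = NULL,
                                specimen_id = mesh$name,
                                plane_normal = "auto", resolution = 0.05,
                                fd = FALSE, spacing = 0.2, radii = 3:20,
                                shape_ratios = NULL) {
  stopifnot(is_triangle_mesh(mesh))
  S <- surface_area(mesh)

  V <- NA_real_
  sv <- NA_real_
  diag <- validate_mesh(mesh)
  if (diag$is_watertight) {
    V <- enclosed_volume(mesh)
    sv <- S / V
  } else {
    cm_info("'", specimen_id, "' is open: V and S/V omitted")
  }

  normal <- NULL
  if (is.character(plane_normal) && identical(plane_normal, "auto")) {
    normal <- tryCatch(estimate_symmetry_plane(mesh), error = function(e) {
      cm_info("'", specimen_id, "': no symmetry plane (", conditionMessage(e),
              "); Sp and rugosity omitted")
      NULL
    })
  } else if (is.numeric(plane_normal)) {
    normal <- unit_vector(plane_normal, "`plane_normal`")
  }
  Sp <- NA_real_
  rug <- NA_real_
  if (!is.null(normal)) {
    Sp <- projected_area(mesh, normal, resolution)
    rug <- tryCatch(S / Sp, error = function(e) NA_real_)
    if (is.finite(Sp) && Sp < resolution^2 * 1.5) {
      cm_info("'", specimen_id, "': degenerate projection; rugosity omitted")
      Sp <- NA_real_
      rug <- NA_real_
    }
  }

  S_ref <- NA_real_
  OI <- NA_real_
  if (!is.null(reference)) {
    stopifnot(is_triangle_mesh(reference))
    S_ref <- surface_area(reference)
    OI <- ornamentation_index(S, S_ref)
  }

  fd_val <- NA_real_
  if (isTRUE(fd)) {
    fd_val <- mfd_for_mesh(mesh, spacing = spacing, radii = radii)$D
  }

  ratios <- list(U_D = NA_real_, W_H = NA_real_, W_D = NA_real_)
  if (!is.null(shape_ratios)) {
    ratios <- modifyList(ratios, as.list(shape_ratios)[
      intersect(names(shape_ratios), names(ratios))
    ])
  }

  metrics_record(
    specimen_id = specimen_id, S = S, S_ref = S_ref, V = V, Sp = Sp,
    OI = OI, sv_ratio = sv, rugosity = rug, fd = fd_val,
    U_D = ratios$U_D, W_H = ratios$W_H, W_D = ratios$W_D
  )
}

significance_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Pairwise Pearson correlation matrix with significance stars
#'
#' Product-moment correlations between metric columns over a table of
#' per-specimen records, with two-sided p-values from the t-transform on
#' `n - 2` degrees of freedom.  Pairs are computed on pairwise-complete
#' observations (open meshes lack S/V, so listwise deletion would be
#' wasteful); the per-pair `n` is reported to keep that visible.  Stars
#' follow the conventional thresholds: `***` p < .001, `**` p < .01, `*`
#' p < .05.  A variable that is constant on the complete pairs gets `NA`
#' (flagged undefined), never zero.
#'
#' @param records Tibble/data frame of metric rows, e.g. from
#'   [compute_all_metrics()].
#' @param variables Character vector of column names to correlate; defaults
#'   to the standard metric columns present with at least 3 non-missing
#'   values.
#' @param adjust `"none"` (default, matching the conventional pairwise
#'   presentation) or `"holm"` to Holm-adjust the p-values before starring.
#' @return A `correlation_matrix` object; see [tidy()] for the long form.
#' @examples
#' df <- tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5))
#' pearson_matrix(df, c("x", "y"))
#' @export
pearson_matrix <- function(records, variables = NULL,
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  records <- tibble::as_tibble(records)
  if (is.null(variables)) {
    cand <- intersect(
      c("OI", "sv_ratio", "rugosity", "fd", "U_D", "W_H", "W_D"),
      names(records)
    )
    variables <- cand[vapply(cand,
      function(v) sum(is.finite(records[[v]])) >= 3L, logical(1)
    )]
  }
  missing_vars <- setdiff(variables, names(records))
  if (length(missing_vars)) {
    stop("variables not present in records: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  k <- length(variables)
  if (k < 2L) stop("need at least 2 variables to correlate", call. = FALSE)
  r <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p <- r
  n <- matrix(NA_integer_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1
  diag(p) <- 0
  flagged <- character(0)
  for (i in seq_len(k)) {
    xi <- records[[variables[i]]]
    n[i, i] <- sum(is.finite(xi))
    for (j in seq_len(k)) {
      if (j <= i) next
      xj <- records[[variables[j]]]
      ok <- is.finite(xi) & is.finite(xj)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3L || sd(xi[ok]) == 0 || sd(xj[ok]) == 0) {
        flagged <- union(flagged, variables[c(i, j)][
          c(sd(xi[ok]) == 0, sd(xj[ok]) == 0)
        ])
        next
      }
      ct <- cor.test(xi[ok], xj[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (length(flagged)) {
    cm_warn("constant variable(s) in correlation: ",
            paste(flagged, collapse = ", "), " (reported as undefined)")
  }
  if (adjust == "holm") {
    up <- upper.tri(p)
    p[up] <- p.adjust(p[up], method = "holm")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  stars <- matrix(significance_stars(p), k, k,
                  dimnames = list(variables, variables))
  diag(stars) <- ""
  structure(
    list(variables = variables, r = r, p = p, n = n, stars = stars,
         adjust = adjust, undefined = flagged),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("<correlation_matrix (Pearson",
      if (x$adjust != "none") paste0(", ", x$adjust, "-adjusted"), ")>\n")
  disp <- matrix(
    paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
    nrow = length(x$variables), dimnames = dimnames(x$r)
  )
  disp[is.na(x$r)] <- "NA"
  print(disp, quote = FALSE)
  invisible(x)
}

#' @method tidy correlation_matrix
#' @export
tidy.correlation_matrix <- function(x, ...) {
  k <- length(x$variables)
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  tibble::tibble(
    var1 = x$variables[idx[, 1]],
    var2 = x$variables[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx],
    stars = x$stars[idx],
    n = as.integer(x$n[idx])
  )
}

#' @method autoplot correlation_matrix
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  df <- tidy(object)
  df_full <- dplyr::bind_rows(
    df,
    dplyr::rename(df, var1 = "var2", var2 = "var1")
  )
  df_full$var1 <- factor(df_full$var1, levels = object$variables)
  df_full$var2 <- factor(df_full$var2, levels = rev(object$variables))
  ggplot2::ggplot(df_full, ggplot2::aes(x = .data$var1, y = .data$var2,
                                        fill = .data$r)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(formatC(.data$r, digits = 2, format = "f"), .data$stars)
    ), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Pairwise Pearson correlations") +
    ggplot2::theme_minimal()
}

#' Write metric and correlation reports
#'
#' Serializes a metrics table (and optionally a correlation matrix) to CSV
#' and/or JSON under `dir`.  The CSV column order is fixed:
#' `specimen_id, S_mm2, Sref_mm2, V_mm3, Sp_mm2, OI_fraction, OI_percent,
#' SV_per_mm, rugosity, MFD_D, U_D, W_H, W_D`; missing values are empty in
#' CSV and `null` in JSON.  OI appears both as the stored fraction and
#' rendered as percent with two decimals.  Correlations are written as JSON
#' and as a long-format CSV (`var1, var2, r, p, stars, n`).
#'
#' @param records Metrics tibble (rows from [compute_all_metrics()]).
#' @param matrix Optional [pearson_matrix()] result.
#' @param dir Output directory (created if needed).
#' @param format Subset of `c("csv", "json")`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(records, matrix = NULL, dir,
                         format = c("csv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory '", dir, "'", call. = FALSE)
  out <- character(0)

  tab <- tibble::as_tibble(records)
  for (col in metrics_columns) {
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
  }
  export <- tibble::tibble(
    specimen_id = tab$specimen_id,
    S_mm2 = tab$S,
    Sref_mm2 = tab$S_ref,
    V_mm3 = tab$V,
    Sp_mm2 = tab$Sp,
    OI_fraction = tab$OI,
    OI_percent = ifelse(is.na(tab$OI), NA_character_,
                        sprintf("%.2f%%", 100 * tab$OI)),
    SV_per_mm = tab$sv_ratio,
    rugosity = tab$rugosity,
    MFD_D = tab$fd,
    U_D = tab$U_D,
    W_H = tab$W_H,
    W_D = tab$W_D
  )
  if ("csv" %in% format) {
    path <- file.path(dir, "metrics.csv")
    readr::write_csv(export, path, na = "")
    out["metrics_csv"] <- path
  }
  if ("json" %in% format) {
    path <- file.path(dir, "metrics.json")
    jsonlite::write_json(export, path, na = "null", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out["metrics_json"] <- path
  }

  if (!is.null(matrix)) {
    stopifnot(inherits(matrix, "correlation_matrix"))
    long <- tidy(matrix)
    if ("csv" %in% format) {
      path <- file.path(dir, "correlations.csv")
      readr::write_csv(long, path, na = "")
      out["correlations_csv"] <- path
    }
    if ("json" %in% format) {
      path <- file.path(dir, "correlations.json")
      jsonlite::write_json(
        list(
          variables = matrix$variables,
          r = matrix$r, p = matrix$p, n = matrix$n, stars = matrix$stars,
          adjust = matrix$adjust
        ),
        path, na = "null", matrix = "rowmajor", digits = NA, pretty = TRUE
      )
      out["correlations_json"] <- path
    }
  }
  invisible(out)
}
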