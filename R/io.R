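#' Read a per-subject multivariate time series from delimited text
#'
#' Rows are time points, columns are nodes; an optional header row gives
#' node labels. The delimiter is inferred from the extension (`.csv`
#' comma, otherwise whitespace/tab). Non-numeric or missing cells raise a
#' descriptive error.
#'
#' @param path File path.
#' @param subject_id Subject identifier stored with the series (default:
#'   file name without extension).
#' @return List with `data` (`nt x V` matrix), `subject_id`, and
#'   `node_labels` (possibly `NULL`).
#' @export
read_bold <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
      class = "dynalocus_invalid_input"
    )
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  first <- utils::read.table(path,
    sep = sep, nrows = 1, header = FALSE,
    colClasses = "character"
  )
  has_header <- anyNA(suppressWarnings(as.numeric(unlist(first))))
  df <- utils::read.table(path, sep = sep, header = has_header)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))),
      arr.ind = TRUE
    )[1, ]
    abort(
      sprintf(
        "Non-numeric cell at row %d, column %d of %s.",
        bad[1], bad[2], path
      ),
      class = "dynalocus_invalid_input"
    )
  }
  if (anyNA(mat) || !all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    abort(
      sprintf(
        "Missing or non-finite value at row %d, column %d of %s.",
        bad[1], bad[2], path
      ),
      class = "dynalocus_invalid_input"
    )
  }
  labels <- if (has_header) colnames(df) else NULL
  id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  list(data = unname(mat), subject_id = id, node_labels = labels)
}

#' Write an analysis result to disk
#'
#' Serializes any package result object (fit, states, reliability table,
#' dFC stack) to an RDS container — read back bit-exactly by
#' [read_result()] — with a human-readable JSON sidecar recording the
#' object class, dimensions, package version, and (for fits) the control
#' parameters.
#'
#' @param x Result object.
#' @param path Output path (conventionally `.rds`); the sidecar is
#'   written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path) {
  payload <- list(
    object = x,
    package_version = as.character(packageVersion("dynalocus"))
  )
  saveRDS(payload, path)
  meta <- list(
    class = class(x)[1],
    package_version = payload$package_version,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  if (!is.null(x$control)) meta$control <- x$control
  if (!is.null(x$N)) meta$dims <- list(N = x$N, T = x$T, V = x$V)
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE,
    pretty = TRUE
  )
  invisible(path)
}

#' Read an analysis result written by [write_result()]
#'
#' @param path Path given to [write_result()].
#' @return The stored object, bit-identical to what was written. A
#'   package-version mismatch produces a warning and a best-effort read.
#' @export
read_result <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
      class = "dynalocus_invalid_input"
    )
  }
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$object)) {
    abort("Not a dynalocus result container.",
      class = "dynalocus_invalid_input"
    )
  }
  current <- as.character(packageVersion("dynalocus"))
  if (!identical(payload$package_version, current)) {
    warn(sprintf(
      "Result written by dynalocus %s, reading with %s.",
      payload$package_version, current
    ))
  }
  payload$object
}

#' Tabular trait report: top edges and node contributions
#'
#' For each trait, ranks edges by absolute signal and retains the top
#' fraction of all `p` edges (ties at the cutoff are all kept), emitting
#' `(trait, node_u, node_v, weight)` rows with node labels when
#' available, plus a per-node contribution-index table.
#'
#' @param fit A `dlocus_fit`.
#' @param top_fraction Fraction of edges retained per trait, in (0, 1).
#' @return List of tibbles `edges` and `nodes`.
#' @export
export_trait_report <- function(fit, top_fraction = 0.005) {
  if (top_fraction <= 0 || top_fraction >= 1) {
    abort("`top_fraction` must lie in (0, 1).",
      class = "dynalocus_invalid_input"
    )
  }
  V <- fit$V
  p <- ncol(fit$S)
  q <- nrow(fit$S)
  labels <- fit$node_labels %||% as.character(seq_len(V))
  # edge endpoints in the package's row-major upper-triangle order
  uu <- unlist(lapply(seq_len(V - 1), function(u) rep(u, V - u)))
  vv <- unlist(lapply(seq_len(V - 1), function(u) (u + 1):V))
  n_keep <- ceiling(top_fraction * p)
  edges <- purrr::map(seq_len(q), function(l) {
    s <- fit$S[l, ]
    ord <- order(abs(s), decreasing = TRUE)
    cutoff <- abs(s[ord[n_keep]])
    keep <- ord[abs(s[ord]) >= cutoff] # ties at the cutoff kept
    tibble::tibble(
      trait = l,
      node_u = labels[uu[keep]], node_v = labels[vv[keep]],
      weight = s[keep]
    )
  })
  nodes <- purrr::map(seq_len(q), function(l) {
    tibble::tibble(
      trait = l, node = labels,
      contribution = node_contribution(fit, l)
    )
  })
  list(edges = dplyr::bind_rows(edges), nodes = dplyr::bind_rows(nodes))
}
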