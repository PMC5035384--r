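#' Construct a landmark set
#'
#' A `landmark_set` holds raw digitized outlines for a sample of specimens:
#' a `k x 2 x n` array of (x, y) coordinates in digitizer units, specimen
#' labels, and optional per-specimen scale factors (digitizer units per
#' physical unit). Scale factors are stored, never pre-applied: Procrustes
#' alignment is scale-invariant, and physical units are only needed when
#' centroid size is to be reported in millimetres.
#'
#' @param coords numeric `k x 2 x n` array (landmarks, xy, specimens), or a
#'   list of `k x 2` matrices.
#' @param ids character vector of specimen labels (recycled from array
#'   dimnames or generated when missing).
#' @param scale optional numeric vector of per-specimen scale factors, all
#'   positive; `NA` allowed for specimens without a SCALE record.
#' @return An object of class `landmark_set` with elements `coords`, `ids`,
#'   `scale`, `k`, `n`.
#' @export
landmark_set <- function(coords, ids = NULL, scale = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    k <- nrow(coords[[1]])
    coords <- array(unlist(lapply(coords, function(m) as.matrix(m))),
                    dim = c(k, 2, length(coords)))
  }
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  if (n > 0L && k < 3L) stop("landmark_set requires k >= 3 landmarks, got ", k)
  if (!all(is.finite(coords))) stop("landmark coordinates must be finite")
  if (is.null(ids)) ids <- dimnames(coords)[[3]]
  if (is.null(ids)) ids <- if (n) paste0("spec_", seq_len(n)) else character()
  if (length(ids) != n) stop("ids length (", length(ids), ") != n specimens (", n, ")")
  if (anyDuplicated(ids)) stop("duplicate specimen ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(scale)) {
    if (length(scale) != n) stop("scale length != n specimens")
    if (any(!is.na(scale) & scale <= 0)) stop("scale factors must be > 0")
  }
  dimnames(coords) <- list(NULL, c("x", "y"), ids)
  structure(list(coords = coords, ids = ids, scale = scale, k = k, n = n),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", x$n, "specimens x", x$k, "landmarks (2-D)\n")
  if (!is.null(x$scale)) cat("  scale factors present for",
                             sum(!is.na(x$scale)), "specimens\n")
  invisible(x)
}

#' @export
`[.landmark_set` <- function(x, i) {
  landmark_set(x$coords[, , i, drop = FALSE], ids = x$ids[i],
               scale = if (!is.null(x$scale)) x$scale[i])
}

#' Read landmark records in the TPS digitizing format
#'
#' Parses the dialect written by the tpsDig family of digitizers: each record
#' starts with `LM=k`, followed by `k` whitespace-separated `x y` lines, then
#' optional `IMAGE=`, `ID=`, `SCALE=` (and other `KEY=value`) lines. Unknown
#' keys are ignored so that dialect drift across digitizer versions does not
#' break parsing. The y axis is kept as digitized (increasing upward); no
#' axis flip is applied. `SCALE=` factors are stored but not applied to the
#' coordinates.
#'
#' @param file path to a TPS file, or a character vector of lines.
#' @return A [landmark_set] with one entry per record, order preserved.
#' @export
read_tps <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n"))
  lines <- trimws(lines)
  lm_at <- grep("^LM=", lines)
  if (length(lm_at) == 0L) {
    if (all(!nzchar(lines))) return(landmark_set(array(0, c(3, 2, 0))))
    stop("no 'LM=' record found in TPS input")
  }
  ends <- c(lm_at[-1] - 1L, length(lines))
  configs <- vector("list", length(lm_at))
  ids <- character(length(lm_at))
  scales <- rep(NA_real_, length(lm_at))
  for (r in seq_along(lm_at)) {
    k <- suppressWarnings(as.integer(sub("^LM=", "", lines[lm_at[r]])))
    if (is.na(k) || k < 0L)
      stop("record ", r, ": malformed LM= header '", lines[lm_at[r]], "'")
    body <- lines[seq(lm_at[r] + 1L, length.out = ends[r] - lm_at[r])]
    body <- body[nzchar(body)]
    is_kv <- grepl("^[A-Za-z]+=", body)
    coord_lines <- body[!is_kv]
    if (length(coord_lines) < k)
      stop("record ", r, ": expected ", k, " coordinate lines, found ",
           length(coord_lines))
    if (length(coord_lines) > k)
      stop("record ", r, ": ", length(coord_lines),
           " coordinate lines exceed LM=", k)
    xy <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      v <- suppressWarnings(as.numeric(strsplit(coord_lines[j], "[[:space:]]+")[[1]]))
      if (length(v) != 2L || anyNA(v))
        stop("record ", r, ", landmark line ", j,
             ": non-numeric or malformed coordinates '", coord_lines[j], "'")
      xy[j, ] <- v
    }
    kv <- body[is_kv]
    id_ln <- grep("^ID=", kv, value = TRUE)
    sc_ln <- grep("^SCALE=", kv, value = TRUE)
    ids[r] <- if (length(id_ln)) sub("^ID=", "", id_ln[1]) else paste0("spec_", r)
    if (length(sc_ln)) {
      s <- suppressWarnings(as.numeric(sub("^SCALE=", "", sc_ln[1])))
      if (is.na(s) || s <= 0) stop("record ", r, ": invalid SCALE '", sc_ln[1], "'")
      scales[r] <- s
    }
    configs[[r]] <- xy
  }
  ks <- vapply(configs, nrow, 1L)
  if (length(unique(ks)) > 1L)
    stop("inconsistent landmark counts across records: ",
         paste(unique(ks), collapse = ", "))
  landmark_set(configs, ids = ids,
               scale = if (any(!is.na(scales))) scales else NULL)
}

#' Write a landmark set in the TPS format
#'
#' Inverse of [read_tps()]: coordinates are written at full precision so that
#' a read-back reproduces the values exactly.
#'
#' @param x a [landmark_set].
#' @param file output path or connection.
#' @return `file`, invisibly.
#' @export
write_tps <- function(x, file) {
  stopifnot(inherits(x, "landmark_set"))
  out <- character()
  for (i in seq_len(x$n)) {
    out <- c(out, paste0("LM=", x$k),
             paste(formatC(x$coords[, 1, i], format = "g", digits = 17),
                   formatC(x$coords[, 2, i], format = "g", digits = 17)))
    if (!is.null(x$scale) && !is.na(x$scale[i]))
      out <- c(out, paste0("SCALE=", formatC(x$scale[i], format = "g", digits = 17)))
    out <- c(out, paste0("ID=", x$ids[i]))
  }
  writeLines(out, file)
  invisible(file)
}

#' Read a semilandmark slider file
#'
#' The slider table lists, for every semilandmark, the two landmarks between
#' which it slides, one `before slider after` triple per row, preceded by a
#' count header (the layout tpsUtil emits). Landmark indices are 1-based in
#' the file and kept 1-based in the returned table.
#'
#' @param file path or character vector of lines.
#' @param k number of landmarks per specimen, for bounds checking.
#' @return A `slider_table`: data.frame with integer columns `before`,
#'   `slider`, `after`.
#' @export
read_sliders <- function(file, k) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) return(slider_table(data.frame(
    before = integer(), slider = integer(), after = integer()), k))
  m <- suppressWarnings(as.integer(lines[1]))
  if (is.na(m)) stop("slider file: first line must be the semilandmark count")
  rows <- lines[-1]
  if (length(rows) != m)
    stop("slider file: header says ", m, " triples but ", length(rows), " rows follow")
  tr <- matrix(NA_integer_, m, 3)
  for (j in seq_len(m)) {
    v <- suppressWarnings(as.integer(strsplit(rows[j], "[[:space:],]+")[[1]]))
    if (length(v) != 3L || anyNA(v))
      stop("slider file row ", j, ": malformed triple '", rows[j], "'")
    tr[j, ] <- v
  }
  slider_table(data.frame(before = tr[, 1], slider = tr[, 2], after = tr[, 3]), k)
}

#' Validate and construct a slider table
#'
#' @param triples data.frame with columns `before`, `slider`, `after`.
#' @param k number of landmarks.
#' @return The validated `slider_table`.
#' @export
slider_table <- function(triples, k) {
  stopifnot(all(c("before", "slider", "after") %in% names(triples)))
  v <- unlist(triples[c("before", "slider", "after")])
  if (nrow(triples) && (any(v < 1L) || any(v > k)))
    stop("slider index out of range [1, ", k, "]")
  if (any(triples$slider == triples$before | triples$slider == triples$after))
    stop("a slider index must differ from its neighbors")
  if (anyDuplicated(triples$slider))
    stop("duplicate slider index: ",
         paste(triples$slider[duplicated(triples$slider)], collapse = ", "))
  structure(triples, class = c("slider_table", "data.frame"), k = k)
}

#' Write a slider table in the count-header triple layout
#' @param sl a `slider_table`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sliders <- function(sl, file) {
  writeLines(c(as.character(nrow(sl)),
               paste(sl$before, sl$slider, sl$after)), file)
  invisible(file)
}

#' Fixed-landmark mask implied by a slider table
#'
#' Fixed landmarks and semilandmarks partition `1..k`: a landmark is fixed
#' exactly when it is not listed as a slider.
#'
#' @param sl a `slider_table`.
#' @param k number of landmarks (defaults to the table's `k` attribute).
#' @return Logical vector of length `k`, `TRUE` for fixed landmarks.
#' @export
fixed_mask <- function(sl, k = attr(sl, "k")) {
  !(seq_len(k) %in% sl$slider)
}

#' Read a specimen trait/fitness table
#'
#' Expects delimited text with a header and (at least) columns
#' `specimen_id`, `episode`, `pw` (pronotum width, the body-size index) and
#' `fitness` (binary mating success or non-negative offspring count).
#'
#' @param file path to a CSV file.
#' @return data.frame with typed, validated columns.
#' @export
read_trait_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("specimen_id", "episode", "pw", "fitness")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait table missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$specimen_id))
    stop("duplicate specimen_id in trait table")
  bad_ep <- setdiff(unique(df$episode), c("mating", "fertilization"))
  if (length(bad_ep)) stop("unknown episode label(s): ",
                           paste(bad_ep, collapse = ", "))
  df$pw <- as.numeric(df$pw)
  df$fitness <- as.numeric(df$fitness)
  if (anyNA(df$pw) || anyNA(df$fitness)) stop("non-numeric pw or fitness value")
  if (any(df$fitness < 0)) stop("negative fitness value")
  df
}
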