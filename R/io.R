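#' Construct a single landmark configuration
#'
#' @param specimen_id character scalar identifying the specimen.
#' @param replicate_id 1-based replicate (digitization) number.
#' @param coords numeric matrix, one landmark per row, 3 columns (x, y, z),
#'   in native digitizer units (typically mm). All values must be finite;
#'   missing landmarks are rejected rather than imputed.
#' @param scheme optional [landmark_scheme()] to validate the landmark count
#'   against.
#' @return object of class `"landmark_config"`.
#' @export
landmark_config <- function(specimen_id, replicate_id, coords, scheme = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z); found ", ncol(coords))
  if (any(!is.finite(coords)))
    stop("configuration for specimen '", specimen_id,
         "' contains missing or non-finite coordinates")
  replicate_id <- as.integer(replicate_id)
  if (is.na(replicate_id) || replicate_id < 1L)
    stop("replicate_id must be a positive integer")
  if (!is.null(scheme) && nrow(coords) != scheme$n_landmarks)
    stop("expected ", scheme$n_landmarks, " landmarks, found ", nrow(coords),
         " (specimen '", specimen_id, "')")
  structure(list(specimen_id = as.character(specimen_id),
                 replicate_id = replicate_id, coords = coords),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration: specimen", x$specimen_id,
      "replicate", x$replicate_id, "-", nrow(x$coords), "x 3 coordinates\n")
  invisible(x)
}

#' Read a 3D Slicer fiducial markup (.fcsv) file
#'
#' Parses the Slicer Markups fiducial CSV dialect: comment header lines
#' beginning with `#` (including an optional `# columns = ...` line naming
#' the fields) followed by one comma-separated row per fiducial point with
#' x, y, z coordinate columns.
#'
#' @param path path to the `.fcsv` file.
#' @param scheme [landmark_scheme()] giving the expected landmark count and
#'   ordering. Row order in the file must match scheme order unless
#'   `label_map` is given.
#' @param specimen_id,replicate_id identifiers for the resulting
#'   configuration; defaults are parsed from the file name
#'   (`<specimen>_rep<k>.fcsv`), falling back to replicate 1.
#' @param label_map optional named integer vector mapping fiducial label
#'   strings to scheme landmark indices, for files whose row order differs
#'   from the scheme.
#' @return a [landmark_config()].
#' @export
read_fcsv <- function(path, scheme, specimen_id = NULL, replicate_id = NULL,
                      label_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  rows <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(rows) != scheme$n_landmarks)
    stop("expected ", scheme$n_landmarks, " landmarks, found ", length(rows),
         " in ", path)
  # locate x,y,z columns from the "# columns = ..." header if present
  xyz <- c(2L, 3L, 4L)
  lab_col <- NA_integer_
  colline <- grep("^#\\s*columns\\s*=", header, value = TRUE)
  if (length(colline)) {
    fields <- trimws(strsplit(sub("^#\\s*columns\\s*=\\s*", "", colline[1]),
                              ",")[[1]])
    pos <- match(c("x", "y", "z"), fields)
    if (!any(is.na(pos))) xyz <- pos
    lab_col <- match("label", fields)
  }
  parts <- strsplit(rows, ",", fixed = TRUE)
  coords <- matrix(NA_real_, length(rows), 3L)
  labels <- character(length(rows))
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < max(xyz))
      stop("row ", i, " of ", path, " has too few fields")
    v <- suppressWarnings(as.numeric(f[xyz]))
    if (any(is.na(v)))
      stop("non-numeric coordinate in row ", i, " of ", path)
    coords[i, ] <- v
    labels[i] <- if (!is.na(lab_col) && length(f) >= lab_col) f[lab_col] else ""
  }
  if (!is.null(label_map)) {
    idx <- label_map[labels]
    if (any(is.na(idx)))
      stop("fiducial labels not covered by label_map: ",
           paste(labels[is.na(idx)], collapse = ", "))
    coords[idx, ] <- coords
  }
  base <- sub("\\.fcsv$", "", basename(path), ignore.case = TRUE)
  if (is.null(specimen_id) || is.null(replicate_id)) {
    m <- regmatches(base, regexec("^(.*)_rep([0-9]+)$", base))[[1]]
    if (length(m) == 3L) {
      if (is.null(specimen_id)) specimen_id <- m[2]
      if (is.null(replicate_id)) replicate_id <- as.integer(m[3])
    } else {
      if (is.null(specimen_id)) specimen_id <- base
      if (is.null(replicate_id)) replicate_id <- 1L
    }
  }
  landmark_config(specimen_id, replicate_id, coords, scheme)
}

#' Write landmark configurations as a Slicer-style .fcsv file
#'
#' @param config a [landmark_config()].
#' @param path output path.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_fcsv <- function(config, path, digits = 6L) {
  hdr <- c("# Markups fiducial file version = 4.11",
           "# CoordinateSystem = LPS",
           "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
  k <- nrow(config$coords)
  rows <- vapply(seq_len(k), function(i) {
    sprintf("vtkMRMLMarkupsFiducialNode_%d,%s,%s,%s,0,0,0,1,1,1,0,LM%d,,",
            i,
            formatC(config$coords[i, 1], digits = digits, format = "f"),
            formatC(config$coords[i, 2], digits = digits, format = "f"),
            formatC(config$coords[i, 3], digits = digits, format = "f"),
            i)
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write TPS landmark files (3D, LM3 blocks)
#'
#' The TPS dialect used here stores one specimen per block: a line
#' `LM3=<k>`, then `k` lines of space-separated x y z coordinates, then
#' `ID=<specimen_id>`. Replicates are encoded by the specimen-ID suffix
#' `_rep<k>` (TPS itself has no replicate field).
#'
#' @param path file path.
#' @param scheme optional [landmark_scheme()]; if supplied the landmark
#'   count of each block is validated against it.
#' @return `read_tps()`: a list of [landmark_config()] (empty, with a
#'   warning, for an empty file).
#' @export
read_tps <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("TPS file is empty: ", path)
    return(list())
  }
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM3=", lines[i]))
      stop("expected 'LM3=' at line ", i, " of ", path, "; found: ", lines[i])
    k <- as.integer(sub("^LM3=", "", lines[i]))
    if (is.na(k) || k < 1L) stop("bad LM3 count at line ", i, " of ", path)
    if (i + k > length(lines))
      stop("LM3=", k, " but only ", length(lines) - i,
           " rows remain in ", path)
    block <- lines[(i + 1L):(i + k)]
    if (any(grepl("^(LM3|ID)=", block)))
      stop("LM3=", k, " does not match coordinate row count near line ", i,
           " of ", path)
    coords <- t(vapply(strsplit(block, "\\s+"), function(f) {
      v <- suppressWarnings(as.numeric(f))
      if (length(v) != 3L || any(is.na(v)))
        stop("malformed coordinate row in ", path, ": ",
             paste(f, collapse = " "))
      v
    }, numeric(3)))
    i <- i + k + 1L
    if (i > length(lines) || !grepl("^ID=", lines[i]))
      stop("missing ID= line after coordinate block in ", path)
    id <- sub("^ID=", "", lines[i])
    i <- i + 1L
    m <- regmatches(id, regexec("^(.*)_rep([0-9]+)$", id))[[1]]
    if (length(m) == 3L) {
      spec <- m[2]; rep <- as.integer(m[3])
    } else {
      spec <- id; rep <- 1L
    }
    configs[[length(configs) + 1L]] <-
      landmark_config(spec, rep, coords, scheme)
  }
  configs
}

#' @rdname read_tps
#' @param configs list of [landmark_config()] to write.
#' @param digits coordinate precision (decimal places).
#' @export
write_tps <- function(configs, path, digits = 6L) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  out <- character(0)
  for (cf in configs) {
    out <- c(out,
             paste0("LM3=", nrow(cf$coords)),
             apply(cf$coords, 1, function(r)
               paste(formatC(r, digits = digits, format = "f"),
                     collapse = " ")),
             paste0("ID=", cf$specimen_id, "_rep", cf$replicate_id))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read and validate a specimen metadata table
#'
#' Expects a CSV with columns `specimen_id, sex, age_at_death,
#' decade_of_birth, matriline, n_hurricanes, age_at_hurricane`. Adds the
#' derived logical `hurricane_experienced` and checks internal consistency:
#' `n_hurricanes > 0` exactly when `age_at_hurricane != "none"`.
#'
#' @param path CSV path, or a data.frame already in memory.
#' @return validated data.frame with typed columns.
#' @export
read_metadata <- function(path) {
  md <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "sex", "age_at_death", "decade_of_birth",
                "matriline", "n_hurricanes", "age_at_hurricane")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols))
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  md$specimen_id <- as.character(md$specimen_id)
  if (anyDuplicated(md$specimen_id))
    stop("duplicated specimen_id in metadata: ",
         paste(unique(md$specimen_id[duplicated(md$specimen_id)]),
               collapse = ", "))
  bad_sex <- setdiff(unique(md$sex), c("F", "M"))
  if (length(bad_sex))
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "),
         " (expected F or M)")
  md$sex <- factor(md$sex, levels = c("F", "M"))
  md$age_at_death <- as.numeric(md$age_at_death)
  if (any(is.na(md$age_at_death)) || any(md$age_at_death < 0))
    stop("age_at_death must be non-negative and non-missing")
  md$decade_of_birth <- as.integer(md$decade_of_birth)
  md$matriline <- factor(md$matriline)
  md$n_hurricanes <- as.integer(md$n_hurricanes)
  if (any(is.na(md$n_hurricanes)) || any(!md$n_hurricanes %in% 0:2))
    stop("n_hurricanes must be 0, 1 or 2")
  bad_age <- setdiff(unique(md$age_at_hurricane),
                     c("fetal", "juvenile", "adult", "none"))
  if (length(bad_age))
    stop("unknown age_at_hurricane value(s): ",
         paste(bad_age, collapse = ", "))
  md$age_at_hurricane <- factor(md$age_at_hurricane,
                                levels = c("fetal", "juvenile", "adult",
                                           "none"))
  md$hurricane_experienced <- md$n_hurricanes > 0L
  inconsistent <- md$hurricane_experienced != (md$age_at_hurricane != "none")
  if (any(inconsistent))
    stop("hurricane fields inconsistent (n_hurricanes vs age_at_hurricane) ",
         "for specimen(s): ",
         paste(md$specimen_id[inconsistent], collapse = ", "))
  md
}

#' Assemble a validated landmark dataset
#'
#' Joins landmark configurations to specimen metadata and checks the design:
#' every specimen must carry the same number of replicate digitizations, and
#' every configuration's specimen must appear in the metadata.
#'
#' @param configs list of [landmark_config()].
#' @param metadata data.frame as returned by [read_metadata()], or `NULL`
#'   for a landmark-only dataset.
#' @param scheme [landmark_scheme()].
#' @return object of class `"fa_dataset"`: list with `scheme`, `configs`,
#'   `metadata`, `n` (individuals) and `r` (replicates per individual).
#' @export
fa_dataset <- function(configs, metadata = NULL, scheme) {
  if (!length(configs)) stop("no landmark configurations supplied")
  for (cf in configs)
    if (nrow(cf$coords) != scheme$n_landmarks)
      stop("configuration for specimen '", cf$specimen_id, "' has ",
           nrow(cf$coords), " landmarks; scheme expects ",
           scheme$n_landmarks)
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  reps <- vapply(configs, `[[`, integer(1), "replicate_id")
  if (anyDuplicated(paste(ids, reps)))
    stop("duplicated (specimen, replicate) configurations")
  tab <- table(ids)
  r <- max(tab)
  if (any(tab != r))
    stop("unequal replicate counts; expected ", r,
         " for all specimens but found fewer for: ",
         paste(names(tab)[tab != r], collapse = ", "))
  if (!is.null(metadata)) {
    metadata <- read_metadata(metadata)
    orphans <- setdiff(unique(ids), metadata$specimen_id)
    if (length(orphans))
      stop("configurations without metadata rows: ",
           paste(orphans, collapse = ", "))
    landless <- setdiff(metadata$specimen_id, unique(ids))
    if (length(landless))
      stop("metadata rows without landmark configurations: ",
           paste(landless, collapse = ", "))
  }
  # canonical ordering: by specimen then replicate, so downstream results
  # do not depend on input file order
  ord <- order(ids, reps)
  structure(list(scheme = scheme, configs = configs[ord],
                 metadata = metadata,
                 n = length(unique(ids)), r = as.integer(r)),
            class = "fa_dataset")
}

#' @export
print.fa_dataset <- function(x, ...) {
  cat("Landmark dataset:", x$n, "individuals x", x$r, "replicates,",
      x$scheme$n_landmarks, "landmarks (", n_pairs(x$scheme), "pairs,",
      n_midline(x$scheme), "midline )\n")
  if (!is.null(x$metadata))
    cat("  metadata:", nrow(x$metadata), "specimens,",
        sum(x$metadata$hurricane_experienced), "hurricane-exposed\n")
  invisible(x)
}

#' Load a dataset from landmark files plus a metadata CSV
#'
#' @param landmarks a directory of `.fcsv`/`.tps` files, a single TPS file,
#'   or a list of [landmark_config()] objects.
#' @param metadata_csv path to the metadata CSV (or data.frame); `NULL` to
#'   skip metadata.
#' @param scheme [landmark_scheme()].
#' @param expected_r if non-`NULL`, error unless every specimen has exactly
#'   this many replicates.
#' @param quiet suppress the summary message.
#' @return an [fa_dataset()].
#' @export
load_dataset <- function(landmarks, metadata_csv = NULL, scheme,
                         expected_r = NULL, quiet = FALSE) {
  configs <- if (is.list(landmarks) && !is.data.frame(landmarks)) {
    landmarks
  } else if (dir.exists(landmarks)) {
    files <- list.files(landmarks, pattern = "\\.(fcsv|tps)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) stop("no .fcsv or .tps files found in ", landmarks)
    out <- list()
    for (f in files) {
      out <- c(out, if (grepl("\\.tps$", f, ignore.case = TRUE))
        read_tps(f, scheme) else list(read_fcsv(f, scheme)))
    }
    out
  } else {
    read_tps(landmarks, scheme)
  }
  ds <- fa_dataset(configs, metadata_csv, scheme)
  if (!is.null(expected_r) && ds$r != expected_r) {
    tab <- table(vapply(ds$configs, `[[`, character(1), "specimen_id"))
    stop("expected ", expected_r, " replicates per specimen, found ", ds$r,
         "; offending specimens: ",
         paste(names(tab)[tab != expected_r], collapse = ", "))
  }
  if (!quiet)
    message("loaded dataset: n = ", ds$n, ", r = ", ds$r,
            ", p = ", n_pairs(scheme), ", u = ", n_midline(scheme))
  ds
}
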