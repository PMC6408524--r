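# Finger-module archives: the pre-characterized one- and two-finger building
# blocks from which five- and six-finger ZFPs are assembled. Triplets are
# stored 5'->3' in target-site orientation: because the finger array runs
# antiparallel to its site, the carboxy-terminal finger binds the 5'-most
# triplet and finger 1 the 3'-most.

TRIPLET_RE <- "^[ACGTMRWSYKVHDBN]{3}$"

.split_triplets <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]

#' Construct a finger module
#'
#' A module is a one- or two-finger unit with the IUPAC DNA triplet(s) it
#' recognizes, given 5'->3' along the target site.
#'
#' @param id Unique module identifier.
#' @param triplets Character vector of 1 or 2 IUPAC triplets (5'->3' in
#'   target-site orientation).
#' @param skip_capable_internal For two-finger modules, whether a 1-bp skip is
#'   permitted between the module's own two fingers. Default `FALSE`.
#' @param helix_labels Optional annotation strings, one per finger.
#' @return A one-row data.frame in archive layout.
#' @export
finger_module <- function(id, triplets, skip_capable_internal = FALSE,
                          helix_labels = NULL) {
  triplets <- toupper(triplets)
  data.frame(
    id = as.character(id),
    n_fingers = length(triplets),
    triplets = paste(triplets, collapse = ","),
    skip_capable_internal = isTRUE(skip_capable_internal),
    helix_labels = if (is.null(helix_labels)) NA_character_ else
      paste(helix_labels, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Construct a module archive
#'
#' @param modules data.frame with columns `id`, `n_fingers`, `triplets`
#'   (comma-joined IUPAC triplets, 5'->3'), `skip_capable_internal`, and
#'   optionally `helix_labels`; typically built by rbind-ing
#'   [finger_module()] rows.
#' @param name Archive name.
#' @param metadata Free-form key/value list.
#' @return An object of class `module_archive`.
#' @export
module_archive <- function(modules, name = "archive", metadata = list()) {
  if (!"helix_labels" %in% names(modules)) modules$helix_labels <- NA_character_
  modules <- modules[, c("id", "n_fingers", "triplets",
                         "skip_capable_internal", "helix_labels")]
  modules$id <- as.character(modules$id)
  modules$helix_labels <- as.character(modules$helix_labels)
  modules$n_fingers <- as.integer(modules$n_fingers)
  modules$skip_capable_internal <- as.logical(modules$skip_capable_internal)
  modules <- modules[order(modules$id), , drop = FALSE]
  rownames(modules) <- NULL
  x <- structure(list(name = name, modules = modules, metadata = metadata),
                 class = "module_archive")
  validate_archive(x)
  x
}

#' Validate a module archive
#'
#' Checks triplet alphabet and length, finger counts, and id uniqueness.
#' Errors name the offending module id.
#'
#' @param archive A `module_archive`.
#' @return The archive, invisibly, if valid.
#' @export
validate_archive <- function(archive) {
  m <- archive$modules
  if (anyDuplicated(m$id)) {
    stop("duplicate module id(s): ",
         paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  }
  for (i in seq_len(nrow(m))) {
    tr <- .split_triplets(m$triplets[i])
    if (!m$n_fingers[i] %in% c(1L, 2L)) {
      stop("module '", m$id[i], "': n_fingers must be 1 or 2")
    }
    if (length(tr) != m$n_fingers[i]) {
      stop("module '", m$id[i], "': ", length(tr), " triplet(s) for ",
           m$n_fingers[i], " finger(s)")
    }
    bad <- tr[!grepl(TRIPLET_RE, tr)]
    if (length(bad)) {
      stop("module '", m$id[i], "': malformed triplet '", bad[1],
           "' (must be 3 IUPAC characters)")
    }
  }
  invisible(archive)
}

#' @export
print.module_archive <- function(x, ...) {
  cat("module_archive '", x$name, "': ", nrow(x$modules), " modules (",
      sum(x$modules$n_fingers == 1L), " one-finger, ",
      sum(x$modules$n_fingers == 2L), " two-finger)\n", sep = "")
  invisible(x)
}

#' Build the GNN module archive
#'
#' The reconstructible reference archive: one one-finger module for each of
#' the 16 GNN triplets (G fixed at the first target position), and one
#' two-finger module for every ordered pair of GNN triplets (16^2 = 256).
#' Module ids are deterministic (`1F_<triplet>`, `2F_<t5>_<t3>` with triplets
#' in 5'->3' site order). `skip_capable_internal` is `FALSE` throughout: skips
#' are demonstrated at inter-module junctions only.
#'
#' @return A `module_archive` with 272 modules.
#' @examples
#' gnn <- build_gnn_archive()
#' table(gnn$modules$n_fingers)
#' @export
build_gnn_archive <- function() {
  bases <- c("A", "C", "G", "T")
  trips <- paste0("G", rep(bases, each = 4), rep(bases, times = 4))
  one <- do.call(rbind, lapply(trips, function(t) finger_module(paste0("1F_", t), t)))
  pairs <- expand.grid(t3 = trips, t5 = trips, stringsAsFactors = FALSE)
  two <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    finger_module(paste0("2F_", pairs$t5[i], "_", pairs$t3[i]),
                  c(pairs$t5[i], pairs$t3[i]))
  }))
  module_archive(rbind(one, two), name = "GNN",
                 metadata = list(source = "built-in GNN set"))
}

.guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("tsv", "json")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
}

#' Save a module archive
#'
#' Serialization is deterministic: modules sorted by id, canonical field
#' order, so save/load/save is byte-identical.
#'
#' @param archive A `module_archive`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`; guessed from the extension if `NULL`.
#' @return `path`, invisibly.
#' @export
save_archive <- function(archive, path, format = NULL) {
  validate_archive(archive)
  format <- .guess_format(path, format)
  m <- archive$modules[order(archive$modules$id), , drop = FALSE]
  if (format == "tsv") {
    hl <- ifelse(is.na(m$helix_labels), "", m$helix_labels)
    lines <- c(
      paste0("# module_archive\tname=", archive$name),
      "id\tn_fingers\ttriplets\tskip_capable_internal\thelix_labels",
      if (nrow(m)) paste(m$id, m$n_fingers, m$triplets,
                         ifelse(m$skip_capable_internal, "TRUE", "FALSE"),
                         hl, sep = "\t")
    )
    writeLines(lines, path)
  } else {
    rownames(m) <- NULL
    obj <- list(name = archive$name, metadata = archive$metadata, modules = m)
    writeLines(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                                pretty = TRUE, na = "null", digits = NA), path)
  }
  invisible(path)
}

#' Load a module archive
#'
#' @param path File written by [save_archive()] (or following its layout).
#' @param format `"tsv"` or `"json"`; guessed from the extension if `NULL`.
#' @return A validated `module_archive`.
#' @export
load_archive <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- .guess_format(path, format)
  if (format == "tsv") {
    lines <- readLines(path)
    name <- "archive"
    if (length(lines) && startsWith(lines[1], "#")) {
      nm <- regmatches(lines[1], regexpr("name=.*$", lines[1]))
      if (length(nm)) name <- sub("^name=", "", nm)
      lines <- lines[-1]
    }
    if (!length(lines)) stop("empty archive file: ", path)
    df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "",
                            na.strings = NULL)
    mods <- data.frame(
      id = df$id,
      n_fingers = as.integer(df$n_fingers),
      triplets = toupper(df$triplets),
      skip_capable_internal = df$skip_capable_internal == "TRUE",
      helix_labels = ifelse(nzchar(df$helix_labels %||% ""), df$helix_labels,
                            NA_character_),
      stringsAsFactors = FALSE
    )
    if (!nrow(df)) mods <- mods[0, ]
    module_archive(mods, name = name)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    mods <- obj$modules
    if (is.null(mods) || !NROW(mods)) {
      mods <- data.frame(id = character(0), n_fingers = integer(0),
                         triplets = character(0),
                         skip_capable_internal = logical(0),
                         helix_labels = character(0))
    }
    module_archive(mods, name = obj$name %||% "archive",
                   metadata = as.list(obj$metadata %||% list()))
  }
}
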