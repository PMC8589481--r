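## Plain-text interchange formats: tab-separated triples and interactions,
## `id<TAB>text` documents, `id<TAB>v1,v2,...` vector tables with a JSON
## side-car header, and numeric-grid (or PNG) images.

#' Read and write knowledge-graph triple files
#'
#' Triple files are headerless tab-separated `head<TAB>relation<TAB>tail`.
#'
#' @param path file path.
#' @param triples data.frame with columns `head`, `relation`, `tail`.
#' @return `read_triples()` returns the triples data.frame.
#' @export
read_triples <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("head", "relation", "tail"))
  x
}

#' @rdname read_triples
#' @export
write_triples <- function(triples, path) {
  utils::write.table(triples[, c("head", "relation", "tail")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write interaction files
#'
#' Headerless tab-separated `user<TAB>item<TAB>label` with labels in {0,1}.
#'
#' @param path file path.
#' @param interactions data.frame with columns `user`, `item`, `label`.
#' @return `read_interactions()` returns the interactions data.frame.
#' @export
read_interactions <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("user", "item", "label"))
  if (!all(x$label %in% c(0L, 1L))) stop_value("labels must be 0 or 1")
  x
}

#' @rdname read_interactions
#' @export
write_interactions <- function(interactions, path) {
  utils::write.table(interactions[, c("user", "item", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write per-entity documents
#'
#' Tab-separated `entity_id<TAB>text`, one document per line.
#'
#' @param path file path.
#' @param documents named list or character vector, entity id -> text.
#' @return `read_documents()` returns a named list of strings.
#' @export
read_documents <- function(path) {
  lines <- readLines(path)
  parts <- regmatches(lines, regexpr("\t", lines), invert = TRUE)
  stats::setNames(as.list(vapply(parts, `[`, "", 2L)),
                  vapply(parts, `[`, "", 1L))
}

#' @rdname read_documents
#' @export
write_documents <- function(documents, path) {
  writeLines(paste(names(documents), unlist(documents), sep = "\t"), path)
  invisible(path)
}

#' Read and write per-id vector tables
#'
#' Rows are `id<TAB>v1,v2,...`; a JSON header at `<path>.json` records the
#' dimension and any model metadata.
#'
#' @param path file path.
#' @param vectors matrix with rownames as ids, or named list of vectors.
#' @param meta named list written into the JSON header.
#' @return `read_vectors()` returns a matrix with id rownames; the header is
#'   attached as attribute `"meta"` when present.
#' @export
read_vectors <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  rows <- lapply(parts, function(p)
    as.numeric(strsplit(p[2L], ",", fixed = TRUE)[[1L]]))
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  hdr <- paste0(path, ".json")
  if (file.exists(hdr))
    attr(out, "meta") <- jsonlite::read_json(hdr, simplifyVector = TRUE)
  out
}

#' @rdname read_vectors
#' @export
write_vectors <- function(vectors, path, meta = list()) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  ids <- rownames(vectors)
  if (is.null(ids)) stop_value("vectors need id rownames")
  vals <- apply(vectors, 1L, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = TRUE), collapse = ","))
  writeLines(paste(ids, vals, sep = "\t"), path)
  meta$dim <- ncol(vectors)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write per-entity images
#'
#' Images are written one file per id under `dir`: plain numeric grids
#' (`.txt`, whitespace-separated rows) by default, or PNG when
#' `format = "png"` and the png package is available.
#'
#' @param dir directory.
#' @param images named list of numeric matrices in \[0, 1\].
#' @param format `"txt"` or `"png"`.
#' @return `read_images()` returns a named list of matrices.
#' @export
write_images <- function(images, dir, format = c("txt", "png")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(images)) {
    if (format == "png") {
      if (!requireNamespace("png", quietly = TRUE))
        stop_value("png package not available; use format = 'txt'")
      png::writePNG(images[[id]], file.path(dir, paste0(id, ".png")))
    } else {
      utils::write.table(images[[id]], file.path(dir, paste0(id, ".txt")),
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_images
#' @export
read_images <- function(dir) {
  files <- list.files(dir, pattern = "\\.(txt|png)$", full.names = TRUE)
  out <- list()
  for (f in files) {
    id <- sub("\\.(txt|png)$", "", basename(f))
    out[[id]] <- if (grepl("\\.png$", f)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop_value("png package not available")
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      m
    } else as.matrix(utils::read.table(f))
  }
  lapply(out, function(m) {
    dimnames(m) <- NULL
    m
  })
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Writes triples, interactions, documents, images and a JSON manifest
#' recording the generator parameters and seed.
#'
#' @param world a [synthetic_world()].
#' @param dir output directory.
#' @param image_format passed to [write_images()].
#' @return the directory, invisibly.
#' @export
write_world <- function(world, dir, image_format = "txt") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_triples(world$triples, file.path(dir, "triples.tsv"))
  write_interactions(world$interactions, file.path(dir, "interactions.tsv"))
  write_documents(world$documents, file.path(dir, "documents.tsv"))
  write_images(world$images, file.path(dir, "images"), image_format)
  jsonlite::write_json(c(world$params, list(seed = world$seed)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
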