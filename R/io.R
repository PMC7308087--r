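# Standard-format I/O: NIfTI (RNifti), FSL bval/bvec, motion-parameter
# tables, GIFTI surfaces and labels (minimal XML reader/writer on xml2;
# ASCII encoding on write, ASCII / Base64 / GZip-Base64 on read), CSV and
# JSON sidecars.

#' Write a volume (3-D or 4-D array) as NIfTI
#'
#' @param data numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param affine 4x4 voxel-to-world matrix.
#' @param sidecar optional list written as a JSON sidecar next to the image
#'   (units and provenance metadata).
#' @return the path, invisibly.
#' @export
write_nifti_map <- function(data, path, affine = diag(4), sidecar = NULL) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sub("\\.nii(\\.gz)?$", ".json", path),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path image path.
#' @return list with `data` (array) and `affine` (4x4 sform).
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Write FSL-style bval/bvec files
#'
#' One whitespace-delimited row of b-values; three rows (x, y, z) of unit
#' direction components.
#'
#' @param scheme an acquisition scheme.
#' @param prefix path prefix; writes `<prefix>.bval` and `<prefix>.bvec`.
#' @return the two paths, invisibly.
#' @export
write_bval_bvec <- function(scheme, prefix) {
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(scheme$bvals, collapse = " "), bval)
  writeLines(apply(t(scheme$bvecs), 1, paste, collapse = " "), bvec)
  invisible(c(bval, bvec))
}

#' Read FSL-style bval/bvec files into an acquisition scheme
#'
#' Pulse timings are not stored in bval/bvec; they are required arguments so
#' the diffusion time is never guessed.
#'
#' @param bval_path,bvec_path file paths.
#' @param small_delta,big_delta pulse timings (ms); mandatory.
#' @return an `acquisition_scheme`.
#' @export
read_bval_bvec <- function(bval_path, bvec_path, small_delta, big_delta) {
  assert_that(!missing(small_delta) && !missing(big_delta),
              "pulse timings are required (they are absent from bval/bvec)")
  bvals <- scan(bval_path, quiet = TRUE)
  m <- do.call(rbind, lapply(readLines(bvec_path), function(l)
    scan(text = l, quiet = TRUE)))
  assert_that(nrow(m) == 3 && ncol(m) == length(bvals),
              "bvec must be 3 rows matching bval length")
  tau <- (big_delta - small_delta / 3) / 1000
  structure(list(bvals = bvals, bvecs = t(m),
                 shell = match(bvals, sort(unique(bvals))) - 1L,
                 small_delta = small_delta / 1000,
                 big_delta = big_delta / 1000, tau = tau,
                 q_magnitudes = sqrt(bvals / tau) / (2 * pi)),
            class = "acquisition_scheme")
}

#' Write / read a motion-parameter table
#'
#' Whitespace-delimited text, frames x 6 (translations mm, rotations rad).
#' @param motion frames x 6 matrix.
#' @param path file path.
#' @return path (write) or matrix (read).
#' @export
write_motion_params <- function(motion, path) {
  utils::write.table(format(motion, digits = 10), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_params
#' @export
read_motion_params <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

# ---- GIFTI ---------------------------------------------------------------
# Minimal GIFTI (.gii) support sufficient for surface + label exchange; no
# installed R package reads this XML format, so it is implemented here on
# xml2. Written files use ASCII encoding (text-only deliverables); the
# reader additionally understands Base64Binary and GZipBase64Binary with
# little-endian payloads.

gifti_data_array <- function(doc, data, intent, datatype) {
  dims <- dim(data) %||% c(length(data))
  da <- xml2::xml_add_child(doc, "DataArray",
                            Intent = intent, DataType = datatype,
                            ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = as.character(length(dims)),
                            Encoding = "ASCII", Endian = "LittleEndian",
                            ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1), as.character(dims[i]))
  txt <- if (is.matrix(data))
    paste(apply(data, 1, paste, collapse = " "), collapse = "\n")
  else paste(data, collapse = " ")
  dn <- xml2::xml_add_child(da, "Data")
  xml2::xml_set_text(dn, txt)
  da
}

#' Write a surface mesh as GIFTI
#'
#' Creates a `.surf.gii` with a POINTSET and a TRIANGLE data array (ASCII
#' encoding, 0-based triangle indices).
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return path, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  gifti_data_array(doc, mesh$vertices, "NIFTI_INTENT_POINTSET",
                   "NIFTI_TYPE_FLOAT32")
  gifti_data_array(doc, mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                   "NIFTI_TYPE_INT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write per-vertex labels as a GIFTI label file
#'
#' Creates a `.label.gii` with a LabelTable mapping integer keys to label
#' names and one NIFTI_INTENT_LABEL data array.
#'
#' @param labels factor or character vector, one entry per vertex.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_gifti_labels <- function(labels, path) {
  labels <- factor(labels)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  lt <- xml2::xml_add_child(doc, "LabelTable")
  for (i in seq_along(levels(labels))) {
    lb <- xml2::xml_add_child(lt, "Label", Key = as.character(i - 1))
    xml2::xml_set_text(lb, levels(labels)[i])
  }
  gifti_data_array(doc, as.integer(labels) - 1L, "NIFTI_INTENT_LABEL",
                   "NIFTI_TYPE_INT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a per-vertex scalar map as a functional GIFTI
#'
#' @param values numeric per-vertex values.
#' @param path output path (.func.gii / .shape.gii).
#' @return path, invisibly.
#' @export
write_gifti_scalars <- function(values, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  gifti_data_array(doc, as.numeric(values), "NIFTI_INTENT_SHAPE",
                   "NIFTI_TYPE_FLOAT32")
  xml2::write_xml(doc, path)
  invisible(path)
}

decode_gifti_data <- function(da) {
  enc <- xml2::xml_attr(da, "Encoding")
  dtype <- xml2::xml_attr(da, "DataType")
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  vals <- switch(
    enc,
    "ASCII" = scan(text = txt, quiet = TRUE),
    "Base64Binary" = ,
    "GZipBase64Binary" = {
      raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
      what <- if (grepl("FLOAT", dtype)) "numeric" else "integer"
      size <- if (grepl("64", dtype) && grepl("FLOAT", dtype)) 8L else 4L
      readBin(raw, what, n = length(raw) / size, size = size,
              endian = "little")
    },
    stop("unsupported GIFTI encoding: ", enc))
  ndim <- as.integer(xml2::xml_attr(da, "Dimensionality"))
  dims <- vapply(seq_len(ndim) - 1L, function(i)
    as.integer(xml2::xml_attr(da, paste0("Dim", i))), integer(1))
  if (length(dims) > 1) {
    # row-major payload -> R column-major
    vals <- t(matrix(vals, nrow = dims[2], ncol = dims[1]))
  }
  list(values = vals, intent = xml2::xml_attr(da, "Intent"), dims = dims)
}

#' Read a GIFTI file
#'
#' Returns the surface mesh, labels, or scalar values depending on the
#' intents present.
#'
#' @param path .gii path.
#' @return For surfaces, a [surface_mesh()]; for label files, a factor; for
#'   scalar files, a numeric vector.
#' @export
read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  das <- lapply(xml2::xml_find_all(doc, ".//DataArray"), decode_gifti_data)
  intents <- vapply(das, `[[`, character(1), "intent")
  if ("NIFTI_INTENT_POINTSET" %in% intents) {
    v <- das[[which(intents == "NIFTI_INTENT_POINTSET")]]$values
    t <- das[[which(intents == "NIFTI_INTENT_TRIANGLE")]]$values
    return(surface_mesh(v, t + 1L))
  }
  if ("NIFTI_INTENT_LABEL" %in% intents) {
    keys <- xml2::xml_find_all(doc, ".//LabelTable/Label")
    names <- xml2::xml_text(keys)
    ids <- as.integer(xml2::xml_attr(keys, "Key"))
    vals <- das[[which(intents == "NIFTI_INTENT_LABEL")]]$values
    return(factor(names[match(vals, ids)], levels = names))
  }
  das[[1]]$values
}

#' Write a parcel summary as CSV
#'
#' @param summary data.frame (subject, hemisphere, subdivision, mean_rtop,
#'   n_vertices).
#' @param path output path.
#' @return path, invisibly.
#' @export
write_parcel_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_summary
#' @export
read_parcel_summary <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an arbitrary result list as JSON
#'
#' @param x list of results (numbers, vectors, data.frames).
#' @param path output path.
#' @return path, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
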