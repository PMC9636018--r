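# Minimal GIFTI-1 reader/writer.
#
# GIFTI is the standard XML surface format of neuroimaging; a file is a set
# of <DataArray> elements whose payload is (optionally compressed)
# base64-encoded binary. Maps are written here as FLOAT64 Base64Binary so
# values round-trip bitwise; FLOAT32/INT32/UINT8 arrays and ASCII /
# Base64Binary / GZipBase64Binary encodings are accepted on read for
# interoperability with files produced by other tools.

gifti_dtypes <- list(
  NIFTI_TYPE_UINT8   = list(what = "integer", size = 1L, signed = FALSE),
  NIFTI_TYPE_INT32   = list(what = "integer", size = 4L, signed = TRUE),
  NIFTI_TYPE_FLOAT32 = list(what = "double",  size = 4L, signed = TRUE),
  NIFTI_TYPE_FLOAT64 = list(what = "double",  size = 8L, signed = TRUE)
)

decode_gifti_data <- function(node, path) {
  dtype <- xml2::xml_attr(node, "DataType")
  enc <- xml2::xml_attr(node, "Encoding")
  endian <- xml2::xml_attr(node, "Endian")
  ndim <- as.integer(xml2::xml_attr(node, "Dimensionality"))
  dims <- vapply(seq_len(max(ndim, 1L)) - 1L, function(d) {
    as.integer(xml2::xml_attr(node, paste0("Dim", d)))
  }, integer(1))
  spec <- gifti_dtypes[[dtype]]
  if (is.null(spec)) stop_format(path, ": unsupported GIFTI DataType '", dtype, "'")
  n <- prod(dims)
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  values <- if (identical(enc, "ASCII")) {
    as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1]])
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw_data <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
    if (identical(enc, "GZipBase64Binary")) {
      raw_data <- tryCatch(memDecompress(raw_data, type = "gzip"),
                           error = function(e) {
                             stop_format(path, ": failed to decompress DataArray: ",
                                         conditionMessage(e))
                           })
    }
    if (length(raw_data) != n * spec$size) {
      stop_format(path, ": DataArray payload has ", length(raw_data),
                  " bytes, expected ", n * spec$size)
    }
    readBin(raw_data, what = spec$what, n = n, size = spec$size,
            signed = spec$signed,
            endian = if (identical(endian, "BigEndian")) "big" else "little")
  } else {
    stop_format(path, ": unsupported GIFTI Encoding '", enc, "'")
  }
  if (length(values) != n) {
    stop_format(path, ": DataArray has ", length(values), " values, expected ", n)
  }
  if (ndim >= 2L) {
    order <- xml2::xml_attr(node, "ArrayIndexingOrder")
    if (identical(order, "ColumnMajorOrder")) {
      values <- matrix(values, nrow = dims[1], ncol = dims[2])
    } else {
      values <- matrix(values, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    }
  }
  list(values = values, intent = xml2::xml_attr(node, "Intent"), dtype = dtype)
}

read_gifti_arrays <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_format(path, ": not parseable as GIFTI XML: ", conditionMessage(e))
  })
  if (!identical(xml2::xml_name(doc), "GIFTI")) {
    stop_format(path, ": root element is <", xml2::xml_name(doc), ">, expected <GIFTI>")
  }
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(nodes) == 0L) stop_format(path, ": no DataArray elements")
  lapply(nodes, decode_gifti_data, path = path)
}

encode_gifti_array <- function(values, intent, dtype) {
  spec <- gifti_dtypes[[dtype]]
  is_mat <- is.matrix(values)
  dims <- if (is_mat) dim(values) else length(values)
  flat <- if (is_mat) as.vector(t(values)) else as.vector(values) # row-major
  if (spec$what == "integer") flat <- as.integer(flat)
  payload <- jsonlite::base64_enc(writeBin(flat, raw(), size = spec$size,
                                           endian = "little"))
  dim_attrs <- paste0(
    sprintf(' Dimensionality="%d" Dim0="%d"', length(dims), dims[1]),
    if (length(dims) > 1L) sprintf(' Dim1="%d"', dims[2]) else ""
  )
  paste0(
    '<DataArray Intent="', intent, '" DataType="', dtype, '"',
    ' ArrayIndexingOrder="RowMajorOrder"', dim_attrs,
    ' Encoding="Base64Binary" Endian="LittleEndian"',
    ' ExternalFileName="" ExternalFileOffset="">\n',
    '<Data>', payload, '</Data>\n</DataArray>\n'
  )
}

write_gifti <- function(path, arrays, label_table = NULL) {
  body <- paste(vapply(arrays, function(a) {
    encode_gifti_array(a$values, a$intent, a$dtype)
  }, character(1)), collapse = "")
  lt <- ""
  if (!is.null(label_table)) {
    lt <- paste0(
      "<LabelTable>\n",
      paste(sprintf('<Label Key="%d"><![CDATA[%s]]></Label>',
                    label_table$key, label_table$label), collapse = "\n"),
      "\n</LabelTable>\n"
    )
  }
  xml_text <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI xmlns="http://www.nitrc.org/frs/download.php/115/gifti.xsd"',
    ' Version="1.0" NumberOfDataArrays="', length(arrays), '">\n',
    lt, body, "</GIFTI>\n"
  )
  writeLines(xml_text, path, sep = "")
  invisible(path)
}

# Placeholder space for maps read without accompanying geometry.
bare_space <- function(n) {
  structure(list(n = as.integer(n)), class = "bare_space")
}
#' @export
n_locations.bare_space <- function(space) space$n
#' @export
space_id.bare_space <- function(space) sprintf("unresolved(%d)", space$n)

#' Read and write scalar surface maps (GIFTI)
#'
#' Scalar maps are stored as one FLOAT64 data array per file
#' (`.func.gii` / `.shape.gii` convention); missing locations (mask
#' `FALSE`) are encoded as NaN on disk, so write-then-read restores both
#' values and mask exactly.
#'
#' @param path file path.
#' @param space optional [spherical_mesh()] the map lives on; when supplied
#'   the vertex count is validated against the file.
#' @return [read_surface_map()] returns a [scalar_map()].
#' @export
read_surface_map <- function(path, space = NULL) {
  arrays <- read_gifti_arrays(path)
  values <- as.numeric(arrays[[1]]$values)
  if (is.null(space)) space <- bare_space(length(values))
  if (length(values) != n_locations(space)) {
    stop_format(path, ": map has ", length(values),
                " vertices but the declared mesh has ", n_locations(space))
  }
  scalar_map(values, space, name = sub("\\.(func|shape)\\.gii$", "", basename(path)))
}

#' @param map a [scalar_map()].
#' @rdname read_surface_map
#' @export
write_surface_map <- function(map, path) {
  values <- map$values
  values[!map$mask] <- NaN
  write_gifti(path, list(list(values = values, intent = "NIFTI_INTENT_NONE",
                              dtype = "NIFTI_TYPE_FLOAT64")))
}

#' Read and write surface geometry (GIFTI)
#'
#' Geometry files (`.surf.gii`) hold a POINTSET array of vertex coordinates
#' and a TRIANGLE array of 0-based face indices.
#'
#' @param path file path.
#' @param hemisphere hemisphere tag to attach on read.
#' @param resolution_id resolution tag to attach on read.
#' @return [read_surface_mesh()] returns a [spherical_mesh()].
#' @export
read_surface_mesh <- function(path, hemisphere = c("left", "right"),
                              resolution_id = NULL) {
  hemisphere <- match.arg(hemisphere)
  arrays <- read_gifti_arrays(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  ip <- match("NIFTI_INTENT_POINTSET", intents)
  it <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(ip) || is.na(it)) {
    stop_format(path, ": geometry file must contain POINTSET and TRIANGLE arrays")
  }
  vertices <- arrays[[ip]]$values
  # Surface templates store coordinates in mm; project to the unit sphere.
  # Already-unit coordinates are left untouched so round-trips are bitwise.
  nrm <- sqrt(rowSums(vertices^2))
  if (max(abs(nrm - 1)) > 1e-9) vertices <- vertices / nrm
  faces <- arrays[[it]]$values + 1L # GIFTI triangles are 0-based
  spherical_mesh(vertices, faces, hemisphere,
                 resolution_id %||% sub("\\.surf\\.gii$", "", basename(path)))
}

#' @param mesh a [spherical_mesh()].
#' @rdname read_surface_mesh
#' @export
write_surface_mesh <- function(mesh, path) {
  write_gifti(path, list(
    list(values = mesh$vertices, intent = "NIFTI_INTENT_POINTSET",
         dtype = "NIFTI_TYPE_FLOAT64"),
    list(values = mesh$faces - 1L, intent = "NIFTI_INTENT_TRIANGLE",
         dtype = "NIFTI_TYPE_INT32")
  ))
}

#' Read and write surface parcellations (GIFTI label files)
#'
#' Label files (`.label.gii`) hold one INT32 array of parcel ids plus a
#' label table; 0 is background.
#'
#' @param path file path.
#' @param space optional [spherical_mesh()] to validate against.
#' @return [read_surface_labels()] returns a [parcellation()].
#' @export
read_surface_labels <- function(path, space = NULL) {
  arrays <- read_gifti_arrays(path)
  labels <- as.integer(arrays[[1]]$values)
  if (is.null(space)) space <- bare_space(length(labels))
  parcellation(labels, space)
}

#' @param parc a [parcellation()].
#' @rdname read_surface_labels
#' @export
write_surface_labels <- function(parc, path) {
  ids <- parcel_ids(parc)
  names <- parc$id_map$name[match(ids, parc$id_map$id)]
  write_gifti(
    path,
    list(list(values = parc$labels, intent = "NIFTI_INTENT_LABEL",
              dtype = "NIFTI_TYPE_INT32")),
    label_table = list(key = c(0L, ids), label = c("background", names))
  )
}
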