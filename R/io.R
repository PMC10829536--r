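#' Serialize a phantom specification to JSON
#'
#' Full-precision JSON (doubles written with enough digits to round-trip
#' bit-exactly).
#'
#' @param spec a \code{phantom_spec}
#' @param path output path
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$conductivity <- as.list(x$conductivity)  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a phantom specification from JSON
#' @param path JSON path written by \code{\link{write_phantom_spec}}
#' @return a \code{phantom_spec}
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) if (is.null(v)) NULL else unlist(v)
  comps <- lapply(x$compartments, function(r) {
    compartment(r$name, r$tissue, r$shape,
                center = num(r$center), semi_axes = num(r$semi_axes),
                lower = num(r$lower), upper = num(r$upper),
                priority = if (is.null(r$priority) || is.na(r$priority))
                  NA_real_ else r$priority)
  })
  cond <- unlist(x$conductivity)
  phantom_spec(comps, cond, spacing = x$spacing,
               bbox = rbind(num(x$bbox[[1]]), num(x$bbox[[2]])),
               seed = x$seed)
}

#' Serialize a patient record to JSON
#' @param rec a \code{patient_record}
#' @param path output path
#' @export
write_patient_record <- function(rec, path) {
  x <- unclass(rec)
  x$active_contact <- as.list(x$active_contact)
  x$impedance_ohm <- as.list(x$impedance_ohm)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a patient record from JSON
#' @param path JSON path
#' @return a \code{patient_record}
#' @export
read_patient_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- list(id = as.integer(x$id),
              active_contact = vapply(x$active_contact, as.integer,
                                      integer(1)),
              current_A = x$current_A,
              pulse_width_us = x$pulse_width_us,
              frequency_Hz = x$frequency_Hz,
              impedance_ohm = vapply(x$impedance_ohm, as.numeric, numeric(1)),
              ybocs_pre = as.integer(x$ybocs_pre),
              ybocs_post = as.integer(x$ybocs_post))
  validate_patient_record(rec)
  structure(rec, class = "patient_record")
}
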