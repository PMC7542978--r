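#' Sensor layout of the 29-channel data glove
#'
#' A `sensor_layout` names the 29 glove channels in canonical order, maps
#' each to a functional role, and records two canonical subsets: the 19
#' channels associated with prehensile in-hand manipulation (all ten finger
#' bends, the four ab/adduction sensors, palm arch, thumb cross, and the
#' pressure sensors P1-P3) and the 12 channels used for the joint network
#' (the ten bends plus palm arch and thumb cross). The 8 orientation
#' (quaternion) channels and pressures P4/P5 are excluded from analysis.
#'
#' @param labels character vector of 29 unique channel names.
#' @param roles named character vector mapping each label to a role.
#' @param relevant19 ordered 19-channel subset of `labels`.
#' @param graph12 ordered 12-channel subset of `relevant19`.
#' @return an object of class `sensor_layout`.
#' @seealso [default_layout()]
#' @export
sensor_layout <- function(labels, roles, relevant19, graph12) {
  labels <- as.character(labels)
  if (length(labels) != 29 || anyDuplicated(labels))
    stopf("layout must have exactly 29 unique channel labels")
  roles <- unlist(roles)[labels]
  if (anyNA(roles))
    stopf("every label needs a role; missing: %s",
          paste(labels[is.na(roles)], collapse = ", "))
  if (length(relevant19) != 19 || !all(relevant19 %in% labels))
    stopf("relevant19 must be 19 channels drawn from labels")
  if (length(graph12) != 12 || !all(graph12 %in% relevant19))
    stopf("graph12 must be 12 channels drawn from relevant19")
  excluded <- setdiff(labels, relevant19)
  if (any(roles[relevant19] == "orientation"))
    stopf("relevant19 may not contain orientation channels")
  structure(list(labels = labels, roles = roles,
                 relevant19 = as.character(relevant19),
                 graph12 = as.character(graph12),
                 excluded = excluded),
            class = "sensor_layout")
}

layout_cache <- new.env(parent = emptyenv())

#' Default glove layout shipped with the package
#'
#' Reads the packaged JSON resource describing the 29 channels (MCP/PIP
#' bends for thumb and four fingers, A1-A4 abduction, palm arch, thumb
#' cross, P1-P5 pressure, and two orientation quaternions).
#'
#' @return a [sensor_layout()].
#' @export
default_layout <- function() {
  if (is.null(layout_cache$default)) {
    path <- system.file("extdata", "sensor_layout.json", package = "gaitglove")
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    layout_cache$default <- sensor_layout(spec$labels, spec$roles,
                                          spec$relevant19, spec$graph12)
  }
  layout_cache$default
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("<sensor_layout> 29 channels;",
      length(x$relevant19), "analysis channels;",
      length(x$graph12), "network channels\n")
  invisible(x)
}

# Sensor groups used for the per-group frequency comparison:
# thumb group includes palm arch, finger MCP and PIP groups have 4 sensors.
sensor_groups <- function(layout = default_layout()) {
  list(Thumb = c("MCP_T", "PIP_T", "Tcross", "PArch"),
       MCP = c("MCP_I", "MCP_M", "MCP_R", "MCP_L"),
       PIP = c("PIP_I", "PIP_M", "PIP_R", "PIP_L"))
}

# Channels whose summed loading fixes the canonical component sign:
# positive means increased bending of thumb cross and/or finger MCP/PIP.
canonical_sign_channels <- function(layout = default_layout()) {
  c("Tcross", "MCP_I", "MCP_M", "MCP_R", "MCP_L",
    "PIP_I", "PIP_M", "PIP_R", "PIP_L")
}
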