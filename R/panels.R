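# Marker panels for the two EV capture protocols.
#
# The immuno-capture protocol profiles 37 surface antigens; the
# MSP-capture protocol profiles only the 14 antigens differentially
# expressed in rejection. Both protocols additionally measure the three
# pan-EV tetraspanins used as the normalization denominator.

#' Tetraspanin markers
#'
#' The three pan-EV tetraspanins (CD9, CD63, CD81) whose mean MFI is the
#' normalization denominator for every sample.
#'
#' @return Character vector of the three tetraspanin marker ids.
#' @export
ev_tetraspanins <- function() c("CD9", "CD63", "CD81")

#' Rejection-associated antigen panel
#'
#' The 14 EV surface antigens differentially expressed across rejection
#' grades; this is the full antigen panel of the MSP-capture protocol and
#' the subset of the immuno-capture panel that carries grade effects in
#' the synthetic generator.
#'
#' @return Character vector of 14 marker ids.
#' @export
ev_affected_markers <- function() {
  c("CD2", "CD3", "CD4", "CD8", "CD19", "CD20", "CD24", "CD25",
    "CD45", "CD49e", "CD62P", "CD142", "CD209", "HLA-I")
}

# 23 additional antigens completing the 37-marker immuno-capture panel.
ev_unaffected_markers <- function() {
  c("CD1c", "CD11c", "CD14", "CD29", "CD31", "CD40", "CD41b", "CD42a",
    "CD44", "CD56", "CD69", "CD86", "CD105", "CD133-1", "CD146",
    "CD326", "HLA-II", "MCSP", "ROR1", "SSEA-4", "CD37", "CD49d", "CD154")
}

#' Antigen panel for a capture protocol
#'
#' @param protocol `"IMMUNO"` (37 antigens) or `"MSP"` (14 antigens).
#' @return Character vector of antigen marker ids (tetraspanins excluded).
#' @export
ev_panel <- function(protocol = c("IMMUNO", "MSP")) {
  protocol <- match.arg(protocol)
  if (protocol == "IMMUNO") c(ev_affected_markers(), ev_unaffected_markers())
  else ev_affected_markers()
}

# All marker columns (tetraspanins first) a protocol's rows must carry.
ev_marker_columns <- function(protocol) c(ev_tetraspanins(), ev_panel(protocol))

# Union of marker columns over protocols, in canonical CSV order.
ev_all_marker_columns <- function() c(ev_tetraspanins(), ev_panel("IMMUNO"))
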