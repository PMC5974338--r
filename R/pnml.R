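## PNML interchange. Core PNML (place / transition / arc / initialMarking /
## inscription) carries the qualitative net; a tool-specific extension
## element (tool = "adspn") carries what core PNML lacks: the arc kind for
## inhibitor / read / equal arcs, the stochastic firing rate per transition,
## optional place capacities, and the bundle's hazard semantics and
## aggregation parameters.

PNML_NS <- "http://www.pnml.org/version-2009/grammar/pnml"

#' Write a model bundle as PNML
#'
#' @param bundle an \code{spn_model}.
#' @param file path to write to.
#' @return the path, invisibly.
#' @seealso \code{\link{read_pnml}}; \code{read_pnml(write_pnml(x))} is
#'   structurally equal to \code{x}.
#' @export
write_pnml <- function(bundle, file) {
  stopifnot(inherits(bundle, "spn_model"))
  net <- bundle$net
  doc <- xml2::xml_new_root("pnml", xmlns = PNML_NS)
  nd <- xml2::xml_add_child(doc, "net", id = bundle$name,
                            type = "http://www.pnml.org/version-2009/grammar/ptnet")
  tx <- function(node, tag, text) {
    ch <- xml2::xml_add_child(node, tag)
    xml2::xml_add_child(ch, "text", text)
    invisible(ch)
  }
  ts <- xml2::xml_add_child(nd, "toolspecific", tool = "adspn",
                            version = "0.1")
  xml2::xml_add_child(ts, "semantics", bundle$semantics)
  for (p in names(bundle$params))
    xml2::xml_add_child(ts, "param", name = p,
                        value = as.character(bundle$params[[p]]))
  page <- xml2::xml_add_child(nd, "page", id = "page0")
  for (i in seq_len(nrow(net$places))) {
    p <- net$places[i, ]
    pn <- xml2::xml_add_child(page, "place", id = p$id)
    tx(pn, "name", p$label)
    tx(pn, "initialMarking", as.character(bundle$marking[[p$id]]))
    if (!is.na(p$capacity)) {
      pts <- xml2::xml_add_child(pn, "toolspecific", tool = "adspn",
                                 version = "0.1")
      xml2::xml_add_child(pts, "capacity", as.character(p$capacity))
    }
  }
  for (i in seq_len(nrow(net$transitions))) {
    t <- net$transitions[i, ]
    tn <- xml2::xml_add_child(page, "transition", id = t$id)
    tx(tn, "name", t$label)
    tts <- xml2::xml_add_child(tn, "toolspecific", tool = "adspn",
                               version = "0.1")
    xml2::xml_add_child(tts, "rate",
                        format(bundle$rates[[t$id]], digits = 15))
  }
  for (i in seq_len(nrow(net$arcs))) {
    a <- net$arcs[i, ]
    an <- xml2::xml_add_child(page, "arc", id = sprintf("a%d", i),
                              source = a$source, target = a$target)
    tx(an, "inscription", as.character(a$weight))
    ats <- xml2::xml_add_child(an, "toolspecific", tool = "adspn",
                               version = "0.1")
    xml2::xml_add_child(ats, "kind", a$kind)
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

xf1 <- function(node, xpath, ns) {
  r <- xml2::xml_find_first(node, xpath, ns)
  if (inherits(r, "xml_missing")) NA_character_ else xml2::xml_text(r)
}

#' Read a PNML model file
#'
#' Accepts documents written by \code{\link{write_pnml}}: core PNML plus the
#' adspn tool-specific extension. Unknown arc kinds and missing transition
#' rates are rejected with the offending element named.
#'
#' @param file path to a PNML file.
#' @return an \code{spn_model} bundle.
#' @export
read_pnml <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- c(p = PNML_NS)
  nd <- xml2::xml_find_first(doc, ".//p:net", ns)
  if (inherits(nd, "xml_missing")) stop("not a PNML document: no <net>")
  name <- xml2::xml_attr(nd, "id")
  semantics <- xf1(nd, "./p:toolspecific/p:semantics", ns)
  if (is.na(semantics)) semantics <- "constant_hazard"
  pars <- xml2::xml_find_all(nd, "./p:toolspecific/p:param", ns)
  params <- stats::setNames(
    lapply(pars, function(x) as.numeric(xml2::xml_attr(x, "value"))),
    vapply(pars, function(x) xml2::xml_attr(x, "name"), ""))
  pnodes <- xml2::xml_find_all(nd, ".//p:place", ns)
  places <- data.frame(
    id = vapply(pnodes, xml2::xml_attr, "", attr = "id"),
    label = vapply(pnodes, xf1, "", xpath = "./p:name/p:text", ns = ns),
    capacity = vapply(pnodes, function(x) {
      v <- xf1(x, "./p:toolspecific/p:capacity", ns)
      if (is.na(v)) NA_integer_ else as.integer(v)
    }, 1L), stringsAsFactors = FALSE)
  m0 <- vapply(pnodes, function(x) {
    v <- xf1(x, "./p:initialMarking/p:text", ns)
    if (is.na(v)) 0L else as.integer(v)
  }, 1L)
  names(m0) <- places$id
  tnodes <- xml2::xml_find_all(nd, ".//p:transition", ns)
  transitions <- data.frame(
    id = vapply(tnodes, xml2::xml_attr, "", attr = "id"),
    label = vapply(tnodes, xf1, "", xpath = "./p:name/p:text", ns = ns),
    stringsAsFactors = FALSE)
  rates <- vapply(tnodes, function(x) {
    v <- xf1(x, "./p:toolspecific/p:rate", ns)
    if (is.na(v))
      stop("transition ", xml2::xml_attr(x, "id"), " has no rate")
    as.numeric(v)
  }, 1)
  names(rates) <- transitions$id
  anodes <- xml2::xml_find_all(nd, ".//p:arc", ns)
  arcs <- data.frame(
    source = vapply(anodes, xml2::xml_attr, "", attr = "source"),
    target = vapply(anodes, xml2::xml_attr, "", attr = "target"),
    kind = vapply(anodes, function(x) {
      v <- xf1(x, "./p:toolspecific/p:kind", ns)
      if (is.na(v)) "standard" else v
    }, ""),
    weight = vapply(anodes, function(x) {
      v <- xf1(x, "./p:inscription/p:text", ns)
      if (is.na(v)) 1L else as.integer(v)
    }, 1L), stringsAsFactors = FALSE)
  bad <- !arcs$kind %in% ARC_KINDS
  if (any(bad))
    stop("unknown arc kind '", arcs$kind[which(bad)[1L]], "' on arc ",
         xml2::xml_attr(anodes[[which(bad)[1L]]], "id"))
  net <- spn(places, transitions, arcs, name = name)
  new_bundle(name, net, m0, rates, semantics = semantics, params = params)
}

#' Write ensemble traces as a long-format CSV table
#'
#' Columns \code{run}, \code{time}, \code{place}, \code{count}, ordered by
#' (run, time, place); times are the ensemble's resampling grid. The file
#' re-reads into an identical table with \code{\link{read_traces_csv}}.
#'
#' @param ens an \code{spn_ensemble}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_traces_csv <- function(ens, file) {
  stopifnot(inherits(ens, "spn_ensemble"))
  if (length(ens$runs) == 0L) stop("empty ensemble")
  tab <- traces_table(ens)
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

## column-major of a place-by-time matrix is already (time slowest, place
## fastest), i.e. rows ordered by (run, time, place)
traces_table <- function(ens) {
  nP <- length(ens$places); nG <- length(ens$grid)
  do.call(rbind, lapply(seq_along(ens$runs), function(i)
    data.frame(run = i,
               time = rep(ens$grid, each = nP),
               place = rep(ens$places, times = nG),
               count = as.integer(ens$runs[[i]]),
               stringsAsFactors = FALSE)))
}

#' Read a traces CSV written by \code{\link{write_traces_csv}}
#'
#' @param file path.
#' @return data frame with columns run, time, place, count.
#' @export
read_traces_csv <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("run", "time", "place", "count")
  if (!all(need %in% names(tab)))
    stop("traces table must have columns ", paste(need, collapse = ", "))
  tab[need]
}
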