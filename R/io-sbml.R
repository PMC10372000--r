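#' SBML Level 3 FBC input and output
#'
#' Reads and writes the subset of SBML L3v1 + FBC v2 needed for
#' constraint-based screening: species, reactions with flux bounds given as
#' parameters, gene products, nested and/or gene-product associations, and
#' flux objectives. Objectives named `biomass` and `atp_maintenance` map onto
#' the model's two screening objectives; if neither name is present the
#' active objective is taken as biomass.
#'
#' Identifiers that are not valid SBML SIds are escaped cobra-style
#' (`__<codepoint>__`), so arbitrary metabolite/reaction/gene ids round-trip.
#'
#' @param path File path.
#' @return `read_sbml_model`: a [metabolic_model].
#' @export
read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  find <- function(node, what) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  }
  attr_any <- function(node, name) {
    at <- xml2::xml_attrs(node)
    hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
    if (length(hit)) at[[hit[1]]] else NA_character_
  }
  model_node <- find(doc, "model")
  if (length(model_node) == 0L) stop("malformed SBML '", path,
                                     "': no <model> element", call. = FALSE)
  model_node <- model_node[[1]]
  model_id <- attr_any(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  params <- find(model_node, "parameter")
  pval <- as.numeric(vapply(params, attr_any, character(1), name = "value"))
  names(pval) <- vapply(params, attr_any, character(1), name = "id")

  species <- find(model_node, "species")
  boundary <- vapply(species, attr_any, character(1),
                     name = "boundaryCondition") %in% "true"
  sp_ids <- vapply(species, attr_any, character(1), name = "id")
  mets <- .sbml_decode(sub("^M_", "", sp_ids[!boundary]))
  names(mets) <- sp_ids[!boundary]

  gp_nodes <- find(model_node, "geneProduct")
  gp_map <- character()
  for (gp in gp_nodes) {
    gid <- attr_any(gp, "id")
    lab <- attr_any(gp, "label")
    gp_map[[gid]] <- if (!is.na(lab) && nzchar(lab)) lab
      else .sbml_decode(sub("^G_", "", gid))
  }

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr_any(node, "geneProduct")
      gene <- if (ref %in% names(gp_map)) gp_map[[ref]]
        else .sbml_decode(sub("^G_", "", ref))
      return(list(kind = "gene", gene = gene))
    }
    if (nm %in% c("and", "or")) {
      kids <- lapply(xml2::xml_children(node), parse_assoc)
      return(.gpr_node(nm, kids))
    }
    stop("malformed SBML '", path, "': unsupported GPR element <", nm, ">",
         call. = FALSE)
  }

  rxn_nodes <- find(model_node, "reaction")
  if (length(rxn_nodes) == 0L) stop("malformed SBML '", path,
                                    "': no reactions", call. = FALSE)
  reactions <- lapply(rxn_nodes, function(rn) {
    rid_raw <- attr_any(rn, "id")
    rid <- .sbml_decode(sub("^R_", "", rid_raw))
    st <- numeric()
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      side_nodes <- xml2::xml_find_all(
        rn, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']",
                    side))
      for (sr in side_nodes) {
        sp <- attr_any(sr, "species")
        if (!sp %in% names(mets)) next  # boundary species are implicit sinks
        coef <- attr_any(sr, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        met <- mets[[sp]]
        st[met] <- (if (met %in% names(st)) st[[met]] else 0) + sgn * coef
      }
    }
    lbid <- attr_any(rn, "lowerFluxBound")
    ubid <- attr_any(rn, "upperFluxBound")
    lb <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]] else -1000
    ub <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]] else 1000
    gpa <- xml2::xml_find_first(
      rn, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) NULL
      else parse_assoc(xml2::xml_child(gpa))
    list(id = rid, stoich = st, lb = lb, ub = ub, gpr = gpr)
  })

  rid_by_raw <- vapply(rxn_nodes, attr_any, character(1), name = "id")
  names(rid_by_raw) <- NULL
  biomass <- NA_character_
  atpm <- NA_character_
  obj_nodes <- find(model_node, "objective")
  active <- NA_character_
  loo <- find(model_node, "listOfObjectives")
  if (length(loo)) active <- attr_any(loo[[1]], "activeObjective")
  for (ob in obj_nodes) {
    oid <- attr_any(ob, "id")
    fo <- xml2::xml_find_first(ob, ".//*[local-name()='fluxObjective']")
    if (inherits(fo, "xml_missing")) next
    rid <- .sbml_decode(sub("^R_", "", attr_any(fo, "reaction")))
    if (identical(oid, "atp_maintenance")) atpm <- rid
    else if (identical(oid, "biomass")) biomass <- rid
    else if (identical(oid, active) && is.na(biomass)) biomass <- rid
  }

  metabolic_model(model_id = .sbml_decode(model_id),
                  metabolites = unname(mets),
                  reactions = reactions,
                  genes = if (length(gp_map)) sort(unique(unname(gp_map)))
                    else NULL,
                  biomass = biomass, atp_maintenance = atpm)
}

#' @rdname read_sbml_model
#' @param model A [metabolic_model].
#' @export
write_sbml_model <- function(model, path) {
  enc <- .sbml_encode
  lines <- character()
  add <- function(...) lines[[length(lines) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
      'level="3" version="1" fbc:required="false">')
  add(sprintf('<model id="%s" fbc:strict="true">', enc(model$id)))
  comps <- unique(vapply(model$mets, .met_compartment, character(1)))
  add("<listOfCompartments>")
  for (cp in comps) {
    add(sprintf('<compartment id="%s" constant="true"/>', enc(cp)))
  }
  add("</listOfCompartments>")
  add("<listOfSpecies>")
  for (m in model$mets) {
    add(sprintf(
      '<species id="M_%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      enc(m), enc(.met_compartment(m))))
  }
  add("</listOfSpecies>")
  bounds <- sort(unique(c(model$lb, model$ub)))
  bnames <- paste0("bnd_", seq_along(bounds))
  names(bnames) <- format(bounds, digits = 17, trim = TRUE, scientific = FALSE)
  add("<listOfParameters>")
  for (i in seq_along(bounds)) {
    add(sprintf(
      '<parameter id="%s" value="%s" constant="true" sboTerm="SBO:0000626"/>',
      bnames[i], format(bounds[i], digits = 17, trim = TRUE,
                        scientific = FALSE)))
  }
  add("</listOfParameters>")
  bname_of <- function(v) bnames[[format(v, digits = 17, trim = TRUE,
                                         scientific = FALSE)]]
  assoc_xml <- function(node) {
    if (node$kind == "gene") {
      return(sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     enc(node$gene)))
    }
    inner <- paste(vapply(node$children, assoc_xml, character(1)),
                   collapse = "")
    sprintf("<fbc:%s>%s</fbc:%s>", node$kind, inner, node$kind)
  }
  add("<listOfReactions>")
  for (rid in model$rxns) {
    st <- model$S[, rid]
    st <- st[st != 0]
    add(sprintf(
      '<reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      enc(rid), tolower(model$lb[[rid]] < 0), bname_of(model$lb[[rid]]),
      bname_of(model$ub[[rid]])))
    gpr <- model$gpr[[rid]]
    if (!is.null(gpr)) {
      add("<fbc:geneProductAssociation>", assoc_xml(gpr),
          "</fbc:geneProductAssociation>")
    }
    reac <- st[st < 0]
    prod <- st[st > 0]
    if (length(reac)) {
      add("<listOfReactants>")
      for (m in names(reac)) {
        add(sprintf(
          '<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          enc(m), format(-reac[[m]], digits = 17, trim = TRUE)))
      }
      add("</listOfReactants>")
    }
    if (length(prod)) {
      add("<listOfProducts>")
      for (m in names(prod)) {
        add(sprintf(
          '<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          enc(m), format(prod[[m]], digits = 17, trim = TRUE)))
      }
      add("</listOfProducts>")
    }
    add("</reaction>")
  }
  add("</listOfReactions>")
  objs <- c(biomass = model$biomass, atp_maintenance = model$atp_maintenance)
  objs <- objs[!is.na(objs)]
  if (length(objs)) {
    add(sprintf('<fbc:listOfObjectives fbc:activeObjective="%s">',
                names(objs)[1]))
    for (i in seq_along(objs)) {
      add(sprintf('<fbc:objective fbc:id="%s" fbc:type="maximize">',
                  names(objs)[i]))
      add("<fbc:listOfFluxObjectives>")
      add(sprintf('<fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
                  enc(objs[[i]])))
      add("</fbc:listOfFluxObjectives>")
      add("</fbc:objective>")
    }
    add("</fbc:listOfObjectives>")
  }
  if (length(model$genes)) {
    add("<fbc:listOfGeneProducts>")
    for (g in model$genes) {
      add(sprintf('<fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                  enc(g), g))
    }
    add("</fbc:listOfGeneProducts>")
  }
  add("</model>")
  add("</sbml>")
  writeLines(lines, path)
  invisible(path)
}

# compartment tag: trailing "[x]" or "_x" single-letter suffix; default "c"
.met_compartment <- function(met) {
  m <- regmatches(met, regexpr("\\[([A-Za-z0-9]+)\\]$", met))
  if (length(m)) return(gsub("\\[|\\]", "", m))
  "c"
}

# escape characters outside [A-Za-z0-9_] as __<codepoint>__ (SId-safe)
.sbml_encode <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(vapply(chars, function(ch) {
      if (grepl("^[A-Za-z0-9_]$", ch)) ch
      else sprintf("__%d__", utf8ToInt(ch))
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.sbml_decode <- function(x) {
  vapply(x, function(s) {
    while (grepl("__([0-9]+)__", s)) {
      m <- regmatches(s, regexpr("__([0-9]+)__", s))
      code <- as.integer(gsub("_", "", m))
      s <- sub("__([0-9]+)__", intToUtf8(code), s)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}
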