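# SBML Level 3 (+ fbc version 2) reader/writer for the subset of SBML this
# package needs: species/compartments, reactions with stoichiometry, flux
# bounds as fbc parameters, GPRs as fbc geneProductAssociation trees (legacy
# GENE_ASSOCIATION notes also accepted on read; fbc wins when both present),
# and the active fbc objective. Full SBML validation is out of scope.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML SId sanitization, cobra-style: non [A-Za-z0-9_] chars become __<code>__
sid_encode <- function(x, prefix) {
  enc <- vapply(x, function(s) {
    chars <- strsplit(s, "")[[1L]]
    paste(vapply(chars, function(ch) {
      if (grepl("^[A-Za-z0-9_]$", ch)) ch else sprintf("__%d__", utf8ToInt(ch))
    }, ""), collapse = "")
  }, "")
  paste0(prefix, enc)
}

sid_decode <- function(x, prefix) {
  x <- sub(paste0("^", prefix), "", x)
  m <- gregexpr("__([0-9]+)__", x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(hits)
    vapply(hits, function(h) intToUtf8(as.integer(gsub("_", "", h))), ""))
  x
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

gpr_to_fbc <- function(node, indent) {
  pad <- strrep(" ", indent)
  if (node$kind == "gene")
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   pad, sid_encode(node$gene, "G_")))
  tag <- if (node$kind == "and") "fbc:and" else "fbc:or"
  inner <- vapply(node$children, gpr_to_fbc, "", indent = indent + 2L)
  paste0(pad, "<", tag, ">\n", paste(inner, collapse = "\n"),
         "\n", pad, "</", tag, ">")
}

model_to_sbml <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  S <- model$stoichiometry
  comps <- unique(mets$compartment)
  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    '  <model id="model" fbc:strict="false">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>',
            sid_encode(comps, "")),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  L <- c(L, sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                           'constant="false" boundaryCondition="false" ',
                           'hasOnlySubstanceUnits="false"/>'),
                    sid_encode(mets$id, "M_"), xml_escape(mets$id),
                    sid_encode(mets$compartment, "")))
  L <- c(L, "    </listOfSpecies>", "    <listOfParameters>")
  rids <- sid_encode(rxns$id, "R_")
  L <- c(L, sprintf('      <parameter id="%s_lb" value="%s" constant="true"/>',
                    rids, format(rxns$lower_bound, digits = 15)),
         sprintf('      <parameter id="%s_ub" value="%s" constant="true"/>',
                 rids, format(rxns$upper_bound, digits = 15)))
  L <- c(L, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(rxns))) {
    co <- as.numeric(S[, i])
    head <- sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" ',
                           'fast="false" fbc:lowerFluxBound="%s_lb" ',
                           'fbc:upperFluxBound="%s_ub">'),
                    rids[i], xml_escape(rxns$id[i]),
                    if (rxns$lower_bound[i] < 0) "true" else "false",
                    rids[i], rids[i])
    L <- c(L, head)
    if (!is.na(rxns$pathway[i]) && nzchar(rxns$pathway[i]))
      L <- c(L,
             "        <notes>",
             '          <body xmlns="http://www.w3.org/1999/xhtml">',
             sprintf("            <p>SUBSYSTEM: %s</p>", xml_escape(rxns$pathway[i])),
             "          </body>",
             "        </notes>")
    spref <- function(idx, tag) {
      if (!length(idx)) return(character())
      c(sprintf("        <listOf%ss>", tag),
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%s" constant="true"/>'),
                sid_encode(mets$id[idx], "M_"),
                format(abs(co[idx]), digits = 15)),
        sprintf("        </listOf%ss>", tag))
    }
    L <- c(L, spref(which(co < 0), "Reactant"), spref(which(co > 0), "Product"))
    if (nzchar(rxns$gpr[i])) {
      ast <- parse_gpr(rxns$gpr[i])
      L <- c(L, "        <fbc:geneProductAssociation>",
             gpr_to_fbc(ast, 10L),
             "        </fbc:geneProductAssociation>")
    }
    L <- c(L, "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>")
  obj <- which(rxns$objective_coefficient != 0)
  L <- c(L,
         '    <fbc:listOfObjectives fbc:activeObjective="obj">',
         '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
         "        <fbc:listOfFluxObjectives>",
         sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                        'fbc:coefficient="%s"/>'),
                 rids[obj], format(rxns$objective_coefficient[obj], digits = 15)),
         "        </fbc:listOfFluxObjectives>",
         "      </fbc:objective>",
         "    </fbc:listOfObjectives>")
  genes <- model_genes(model)
  if (length(genes)) {
    L <- c(L, "    <fbc:listOfGeneProducts>",
           sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                   sid_encode(genes, "G_"), xml_escape(genes)),
           "    </fbc:listOfGeneProducts>")
  }
  c(L, "  </model>", "</sbml>")
}

# namespace-agnostic helpers: SBML in the wild varies in prefixes
xfind <- function(node, localname) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", localname))
}

xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hits <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (!length(hits)) NA_character_ else unname(at[hits[1L]])
}

fbc_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)  # xml_name drops the prefix
  if (nm == "geneProductRef")
    return(structure(list(kind = "gene",
                          gene = sid_decode(xattr(node, "geneProduct"), "G_")),
                     class = "gpr_node"))
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    kids <- kids[xml2::xml_name(kids) %in% c("and", "or", "geneProductRef")]
    children <- lapply(kids, fbc_to_gpr)
    if (length(children) == 1L) return(children[[1L]])
    return(structure(list(kind = nm, children = gpr_flatten(children, nm)),
                     class = "gpr_node"))
  }
  stop("unexpected element in geneProductAssociation: ", nm)
}

sbml_to_model <- function(text) {
  doc <- tryCatch(xml2::read_xml(text), error = function(e)
    stop("not well-formed XML/SBML: ", conditionMessage(e)))
  if (xml2::xml_name(doc) != "sbml")
    stop("root element is '", xml2::xml_name(doc), "', not an SBML document")

  sp <- xfind(doc, "species")
  met_sid <- vapply(sp, function(n) xattr(n, "id"), "")
  mets <- data.frame(
    id = sid_decode(met_sid, "M_"),
    compartment = vapply(sp, function(n) {
      cp <- xattr(n, "compartment"); if (is.na(cp)) "c" else sid_decode(cp, "")
    }, ""),
    stringsAsFactors = FALSE)

  pars <- xfind(doc, "parameter")
  parval <- stats::setNames(
    vapply(pars, function(n) as.numeric(xattr(n, "value")), 0),
    vapply(pars, function(n) xattr(n, "id"), ""))

  gps <- xfind(doc, "geneProduct")
  glabel <- stats::setNames(
    vapply(gps, function(n) {
      lb <- xattr(n, "label")
      if (is.na(lb) || !nzchar(lb)) sid_decode(xattr(n, "id"), "G_") else lb
    }, ""),
    vapply(gps, function(n) xattr(n, "id"), ""))

  rnodes <- xfind(doc, "reaction")
  n <- length(rnodes)
  if (!n) stop("SBML document contains no reactions")
  rid <- character(n); lb <- numeric(n); ub <- numeric(n)
  gpr <- character(n); pw <- rep(NA_character_, n)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (k in seq_len(n)) {
    node <- rnodes[[k]]
    sid <- xattr(node, "id")
    rid[k] <- sid_decode(sid, "R_")
    rev <- identical(xattr(node, "reversible"), "true")
    lbp <- xattr(node, "lowerFluxBound"); ubp <- xattr(node, "upperFluxBound")
    lb[k] <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]]
             else if (rev) -1000 else 0
    ub[k] <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000

    for (side in list(c("listOfReactants", -1), c("listOfProducts", 1))) {
      lo <- xml2::xml_find_first(node,
              sprintf("./*[local-name()='%s']", side[[1L]]))
      if (inherits(lo, "xml_missing")) next
      for (sr in xml2::xml_children(lo)) {
        sp_id <- xattr(sr, "species")
        st <- xattr(sr, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        midx <- match(sid_decode(sp_id, "M_"), mets$id)
        if (is.na(midx))
          stop("reaction '", rid[k], "' references undeclared species ", sp_id)
        ii <- c(ii, midx); jj <- c(jj, k)
        xx <- c(xx, as.numeric(side[[2L]]) * st)
      }
    }

    gpa <- xml2::xml_find_first(node,
             "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) {
        ast <- fbc_to_gpr(kids[[1L]])
        ast <- gpr_relabel(ast, glabel)
        gpr[k] <- gpr_text(ast)
      }
    }
    notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
    if (!inherits(notes, "xml_missing")) {
      nt <- xml2::xml_text(notes)
      if (!nzchar(gpr[k])) {
        m <- regmatches(nt, regexec("GENE[_ ]ASSOCIATION:\\s*([^\n]+)", nt))[[1L]]
        if (length(m) == 2L) {
          cand <- trimws(m[2L])
          parsed <- tryCatch(parse_gpr(cand), error = function(e) NULL)
          if (!is.null(parsed)) gpr[k] <- cand
        }
      }
      m <- regmatches(nt, regexec("SUBSYSTEM:\\s*([^\n]+)", nt))[[1L]]
      if (length(m) == 2L && nzchar(trimws(m[2L]))) pw[k] <- trimws(m[2L])
    }
  }

  oc <- rep(0, n)
  for (fo in xfind(doc, "fluxObjective")) {
    rref <- xattr(fo, "reaction")
    co <- as.numeric(xattr(fo, "coefficient"))
    idx <- match(sid_decode(rref, "R_"), rid)
    if (!is.na(idx)) oc[idx] <- co
  }

  # validate each GPR, naming the offending reaction
  for (k in seq_len(n)) {
    if (nzchar(gpr[k]))
      tryCatch(parse_gpr(gpr[k]), error = function(e)
        stop("GPR of reaction '", rid[k], "' fails to parse: ",
             conditionMessage(e)))
  }

  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(mets), n),
                            dimnames = list(mets$id, rid))
  metabolic_model(mets,
                  data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                             gpr = gpr, objective_coefficient = oc,
                             pathway = pw, stringsAsFactors = FALSE),
                  S)
}

# replace fbc gene-product ids with their labels (original gene ids)
gpr_relabel <- function(node, glabel) {
  if (node$kind == "gene") {
    sid <- sid_encode(node$gene, "G_")
    if (sid %in% names(glabel)) node$gene <- unname(glabel[[sid]])
    return(node)
  }
  node$children <- lapply(node$children, gpr_relabel, glabel = glabel)
  node
}
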