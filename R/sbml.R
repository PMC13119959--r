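# SBML Level 2 Version 4 export of the microbial phenazine subsystem.
#
# The exported model covers continuous batch operation: the four microbial
# balances plus first-order electrode oxidation of P_red, encoded as rate
# rules over assignment-rule intermediates, and (optionally) a cumulative
# capacity parameter whose rate equals the instantaneous current density.
# Cycling logic (voltage cut-off, imposed recharge current) is deliberately
# not encoded: it would require events and lies outside the exported
# subsystem.

.SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# exact-precision number formatting (round-trips doubles bit-exactly)
.sbml_num <- function(x) sprintf("%.17g", x)

# ---- R expression <-> content MathML ---------------------------------------

.expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(sprintf("<cn type=\"real\"> %s </cn>", .sbml_num(e)))
  if (is.name(e)) return(sprintf("<ci> %s </ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(.expr_to_mathml(e[[2L]]))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", "log" = "ln", "exp" = "exp",
                  stop("unsupported operator in MathML export: ", op))
    args <- vapply(as.list(e)[-1L], .expr_to_mathml, character(1L))
    return(sprintf("<apply><%s/>%s</apply>", tag, paste(args, collapse = "")))
  }
  stop("unsupported expression in MathML export")
}

.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("malformed <math> element")
    return(.mathml_to_expr(kids[[1L]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    kids <- xml2::xml_children(node)
    if (length(kids) > 0L && xml2::xml_name(kids[[1L]]) == "sep") {
      # rational or e-notation form: mantissa <sep/> exponent
      parts <- strsplit(xml2::xml_text(node), "\\s+")[[1L]]
      parts <- parts[nzchar(parts)]
      typ <- xml2::xml_attr(node, "type")
      a <- as.numeric(parts[1L]); b <- as.numeric(parts[2L])
      return(if (identical(typ, "rational")) a / b else a * 10^b)
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1L]])
    fn <- switch(op, plus = "+", minus = "-", times = "*", divide = "/",
                 power = "^", ln = "log", exp = "exp",
                 stop("unsupported MathML operator: ", op))
    args <- lapply(kids[-1L], .mathml_to_expr)
    if (fn %in% c("+", "*") && length(args) > 2L)   # n-ary fold
      return(Reduce(function(a, b) call(fn, a, b), args))
    return(do.call(call, c(list(fn), args), quote = TRUE))
  }
  stop("unsupported MathML element: ", nm)
}

# ---- model specification ----------------------------------------------------

#' Specification of the exportable microbial phenazine subsystem
#'
#' Bundles the microbial parameters, the electrochemical subset needed for
#' the electrode flux and capacity terms (k_elec, A, n_e, F), the initial
#' state, and whether to include the cumulative-capacity variable.
#'
#' @param microbial A [microbial_params()].
#' @param electro An [electro_params()] (only `k_elec`, `A`, `n_e`, `F_C`
#'   are exported).
#' @param initial An [anolyte_state()].
#' @param include_capacity Include the cumulative discharge-capacity
#'   parameter `Q_cap` (A h m^-2) governed by a rate rule equal to the
#'   instantaneous current density. Default `TRUE`.
#' @return An object of class `sbml_model_spec`.
#' @export
sbml_model_spec <- function(microbial = microbial_params(),
                            electro = electro_params(),
                            initial = anolyte_state(),
                            include_capacity = TRUE) {
  bad <- character(0)
  if (!inherits(microbial, "microbial_params")) bad <- c(bad, "microbial")
  if (!inherits(electro, "electro_params")) bad <- c(bad, "electro")
  if (!inherits(initial, "anolyte_state")) bad <- c(bad, "initial")
  if (!is.logical(include_capacity) || length(include_capacity) != 1L ||
      is.na(include_capacity)) bad <- c(bad, "include_capacity")
  if (inherits(microbial, "microbial_params") && !is.finite(microbial$K_inh))
    bad <- c(bad, "microbial$K_inh (must be finite for SBML export)")
  if (length(bad))
    stop("sbml_model_spec: invalid field(s): ", paste(bad, collapse = ", "))
  structure(list(microbial = microbial, electro = electro, initial = initial,
                 include_capacity = include_capacity),
            class = "sbml_model_spec")
}

# rule set of the exported subsystem (single source for export and docs)
.sbml_rules <- function(include_capacity = TRUE) {
  assignment <- list(
    P_tot  = quote(P_red + P_ox),
    q_S    = quote(qS_max * S / (K_S + S)),
    f_tox  = quote(1 / (1 + (P_tot / K_inh)^n_inh)),
    mu     = quote(Y_XS * q_S * f_tox),
    r_prod = quote((alpha_P * mu + beta_P) * X),
    v_elec = quote(k_elec * P_red),
    j      = quote(n_e * F_const * v_elec / (A_elec * 1000 * 3600))
  )
  rate <- list(
    X     = quote(mu * X),
    S     = quote(-(q_S * X)),
    P_red = quote(r_prod - v_elec - k_deg * P_red),
    P_ox  = quote(v_elec - k_deg * P_ox)
  )
  if (include_capacity) rate$Q_cap <- quote(j)
  list(assignment = assignment, rate = rate)
}

#' Export the microbial phenazine subsystem as SBML Level 2 Version 4
#'
#' Serializes the continuous batch subsystem: species `X` (biomass, gram dry
#' weight per litre, declared with gram substance units since SBML has no
#' dry-weight unit), `S`, `P_red`, `P_ox` (mmol L^-1), the kinetic and
#' electrode constants as parameters, the intermediate quantities (Monod
#' uptake, Hill toxicity factor, effective growth rate, production rate,
#' electrode flux, current density) as assignment rules, the four balances
#' as rate rules, and optionally the cumulative capacity `Q_cap` (A h m^-2)
#' with rate equal to the current density.
#'
#' @param spec An [sbml_model_spec()].
#' @param file Optional path; when given the document is written there.
#' @return The SBML document as a single character string (invisibly when
#'   `file` is given).
#' @examples
#' doc <- export_sbml(sbml_model_spec())
#' validate_sbml(doc)$errors   # character(0)
#' @export
export_sbml <- function(spec, file = NULL) {
  stopifnot(inherits(spec, "sbml_model_spec"))
  mp <- spec$microbial; ep <- spec$electro; st <- spec$initial
  rules <- .sbml_rules(spec$include_capacity)

  consts <- c(qS_max = mp$qS_max, K_S = mp$K_S, Y_XS = mp$Y_XS,
              alpha_P = mp$alpha_P, beta_P = mp$beta_P, k_deg = mp$k_deg,
              K_inh = mp$K_inh, n_inh = mp$n_inh,
              k_elec = ep$k_elec, A_elec = ep$A, n_e = ep$n_e,
              F_const = ep$F_C)
  derived <- c("P_tot", "q_S", "f_tox", "mu", "r_prod", "v_elec", "j")

  param_xml <- c(
    vapply(names(consts), function(nm) sprintf(
      "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
      nm, .sbml_num(consts[[nm]])), character(1L)),
    vapply(derived, function(nm) sprintf(
      "      <parameter id=\"%s\" value=\"0\" constant=\"false\"/>",
      nm), character(1L)),
    if (spec$include_capacity)
      "      <parameter id=\"Q_cap\" value=\"0\" constant=\"false\"/>"
  )

  species <- rbind(
    data.frame(id = "X", conc = st$X, sub = "gram"),
    data.frame(id = "S", conc = st$S, sub = "substance"),
    data.frame(id = "P_red", conc = st$P_red, sub = "substance"),
    data.frame(id = "P_ox", conc = st$P_ox, sub = "substance"))
  species_xml <- vapply(seq_len(nrow(species)), function(i) sprintf(
    paste0("      <species id=\"%s\" compartment=\"anolyte\" ",
           "initialConcentration=\"%s\" substanceUnits=\"%s\" ",
           "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
           "constant=\"false\"/>"),
    species$id[i], .sbml_num(species$conc[i]), species$sub[i]),
    character(1L))

  rule_xml <- c(
    vapply(names(rules$assignment), function(v) sprintf(
      "      <assignmentRule variable=\"%s\">\n        <math xmlns=\"%s\">%s</math>\n      </assignmentRule>",
      v, .MATHML_NS, .expr_to_mathml(rules$assignment[[v]])), character(1L)),
    vapply(names(rules$rate), function(v) sprintf(
      "      <rateRule variable=\"%s\">\n        <math xmlns=\"%s\">%s</math>\n      </rateRule>",
      v, .MATHML_NS, .expr_to_mathml(rules$rate[[v]])), character(1L)))

  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    sprintf("<sbml xmlns=\"%s\" level=\"2\" version=\"4\">\n", .SBML_NS),
    "  <model id=\"phenazine_bioanolyte\" name=\"Phenazine-producing E. coli bio-anolyte (batch subsystem)\">\n",
    "    <notes>\n",
    "      <body xmlns=\"http://www.w3.org/1999/xhtml\">\n",
    "        <p>Zero-dimensional microbial phenazine subsystem: Monod substrate\n",
    "        uptake, Hill-type growth inhibition by total phenazine,\n",
    "        growth-associated (Luedeking-Piret) phenazine production,\n",
    "        first-order mediator degradation, and first-order electrode\n",
    "        oxidation of reduced phenazine. Concentrations in mmol/L; biomass\n",
    "        X is gram dry weight per litre, declared with gram substance\n",
    "        units. Time in hours. Q_cap accumulates discharge capacity in\n",
    "        A h per m2 of electrode.</p>\n",
    "      </body>\n",
    "    </notes>\n",
    "    <listOfUnitDefinitions>\n",
    "      <unitDefinition id=\"time\">\n",
    "        <listOfUnits><unit kind=\"second\" multiplier=\"3600\"/></listOfUnits>\n",
    "      </unitDefinition>\n",
    "      <unitDefinition id=\"substance\">\n",
    "        <listOfUnits><unit kind=\"mole\" scale=\"-3\"/></listOfUnits>\n",
    "      </unitDefinition>\n",
    "      <unitDefinition id=\"volume\">\n",
    "        <listOfUnits><unit kind=\"litre\"/></listOfUnits>\n",
    "      </unitDefinition>\n",
    "    </listOfUnitDefinitions>\n",
    "    <listOfCompartments>\n",
    "      <compartment id=\"anolyte\" size=\"1\" units=\"volume\"/>\n",
    "    </listOfCompartments>\n",
    "    <listOfSpecies>\n",
    paste(species_xml, collapse = "\n"), "\n",
    "    </listOfSpecies>\n",
    "    <listOfParameters>\n",
    paste(param_xml, collapse = "\n"), "\n",
    "    </listOfParameters>\n",
    "    <listOfRules>\n",
    paste(rule_xml, collapse = "\n"), "\n",
    "    </listOfRules>\n",
    "  </model>\n",
    "</sbml>\n")

  xml2::read_xml(doc)  # well-formedness check before handing it out
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

# read an SBML document from a string, file path, or xml2 object
.sbml_read <- function(document) {
  x <- if (inherits(document, "xml_document")) document
  else if (is.character(document) && length(document) == 1L &&
           !grepl("<", document, fixed = TRUE) && file.exists(document))
    xml2::read_xml(document)
  else xml2::read_xml(paste(document, collapse = "\n"))
  x
}

#' Parse an SBML document into parameters, species and rules
#'
#' Generic reader for SBML Level 2 rate-rule models: extracts constant and
#' non-constant parameters (with values), species initial concentrations,
#' compartment sizes, and the assignment and rate rules as R expressions
#' translated from content MathML.
#'
#' @param document SBML as a character string, a file path, or an
#'   `xml2::xml_document`.
#' @return A list with `level`, `version`, `parameters` (named numeric,
#'   constants), `variables` (named numeric, non-constant parameters with
#'   initial values), `species` (named numeric initial concentrations),
#'   `compartments` (named numeric sizes), `assignment_rules` and
#'   `rate_rules` (named lists of unevaluated R expressions, in document
#'   order).
#' @export
parse_sbml <- function(document) {
  x <- .sbml_read(document)
  root <- x
  level <- xml2::xml_attr(root, "level")
  version <- xml2::xml_attr(root, "version")
  xml2::xml_ns_strip(x)
  model <- xml2::xml_find_first(x, ".//model")
  if (inherits(model, "xml_missing")) stop("parse_sbml: no <model> element")

  grab <- function(xpath, attr) {
    nodes <- xml2::xml_find_all(model, xpath)
    vals <- as.numeric(xml2::xml_attr(nodes, attr))
    names(vals) <- xml2::xml_attr(nodes, "id")
    vals
  }
  pars_all <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  is_const <- !(xml2::xml_attr(pars_all, "constant") %in% "false")
  pvals <- as.numeric(xml2::xml_attr(pars_all, "value"))
  pids <- xml2::xml_attr(pars_all, "id")

  read_rules <- function(tag) {
    nodes <- xml2::xml_find_all(model, paste0(".//listOfRules/", tag))
    out <- lapply(nodes, function(nd)
      .mathml_to_expr(xml2::xml_find_first(nd, "./math")))
    names(out) <- xml2::xml_attr(nodes, "variable")
    out
  }

  list(level = level, version = version,
       parameters = stats::setNames(pvals[is_const], pids[is_const]),
       variables = stats::setNames(pvals[!is_const], pids[!is_const]),
       species = grab(".//listOfSpecies/species", "initialConcentration"),
       compartments = grab(".//listOfCompartments/compartment", "size"),
       assignment_rules = read_rules("assignmentRule"),
       rate_rules = read_rules("rateRule"))
}

#' Internal-consistency check of an SBML document
#'
#' Structural and semantic lint for Level 2 rate-rule models: XML
#' well-formedness, declared level/version, presence of a model, id
#' uniqueness, that every rule variable is a declared non-constant entity,
#' that every symbol referenced in rule math is declared, and that species
#' reference declared compartments. Sign checks on constant parameters
#' (e.g. a negative half-saturation constant) are reported as warnings.
#'
#' @param document SBML as a string, file path or `xml2::xml_document`.
#' @return A list with character vectors `errors` and `warnings`; both empty
#'   for a freshly exported document.
#' @export
validate_sbml <- function(document) {
  errors <- character(0); warnings <- character(0)
  x <- tryCatch(.sbml_read(document), error = function(e) e)
  if (inherits(x, "error"))
    return(list(errors = paste("XML parse error:", conditionMessage(x)),
                warnings = character(0)))
  if (xml2::xml_name(x) != "sbml")
    errors <- c(errors, "root element is not <sbml>")
  lv <- xml2::xml_attr(x, "level"); vs <- xml2::xml_attr(x, "version")
  if (!identical(lv, "2"))
    errors <- c(errors, paste0("unsupported SBML level: ", lv))
  if (identical(lv, "2") && !identical(vs, "4"))
    warnings <- c(warnings, paste0("expected Level 2 Version 4, found version ", vs))

  p <- tryCatch(parse_sbml(x), error = function(e) e)
  if (inherits(p, "error"))
    return(list(errors = c(errors, paste("structural error:",
                                         conditionMessage(p))),
                warnings = warnings))

  ids <- c(names(p$parameters), names(p$variables), names(p$species),
           names(p$compartments))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    errors <- c(errors, paste0("duplicate id(s): ", paste(dup, collapse = ", ")))

  xml2::xml_ns_strip(x)
  model <- xml2::xml_find_first(x, ".//model")
  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  missing_comp <- setdiff(sp_comp, names(p$compartments))
  if (length(missing_comp))
    errors <- c(errors, paste0("species reference undeclared compartment(s): ",
                               paste(missing_comp, collapse = ", ")))

  # rule variables must be declared and assignable
  assignable <- c(names(p$variables), names(p$species))
  for (v in names(c(p$assignment_rules, p$rate_rules))) {
    if (!(v %in% ids))
      errors <- c(errors, paste0("rule variable '", v, "' is not declared"))
    else if (v %in% names(p$parameters))
      errors <- c(errors, paste0("rule variable '", v,
                                 "' is declared constant"))
  }
  # every symbol used in rule math must resolve
  for (nm in names(p$assignment_rules))
    for (sym in all.vars(p$assignment_rules[[nm]]))
      if (!(sym %in% ids))
        errors <- c(errors, paste0("assignment rule for '", nm,
                                   "' references undeclared symbol '", sym, "'"))
  for (nm in names(p$rate_rules))
    for (sym in all.vars(p$rate_rules[[nm]]))
      if (!(sym %in% ids))
        errors <- c(errors, paste0("rate rule for '", nm,
                                   "' references undeclared symbol '", sym, "'"))
  # assignment-rule variables must not also have rate rules
  both <- intersect(names(p$assignment_rules), names(p$rate_rules))
  if (length(both))
    errors <- c(errors, paste0("variable(s) governed by two rules: ",
                               paste(both, collapse = ", ")))

  neg <- names(p$parameters)[is.finite(p$parameters) & p$parameters < 0]
  neg <- setdiff(neg, c("E0_an", "E_cath"))  # potentials may be negative
  if (length(neg))
    warnings <- c(warnings,
                  paste0("constant parameter(s) with negative value: ",
                         paste(neg, collapse = ", "),
                         " (kinetic constants are expected to be positive)"))
  negS <- names(p$species)[is.finite(p$species) & p$species < 0]
  if (length(negS))
    errors <- c(errors, paste0("negative initial concentration(s): ",
                               paste(negS, collapse = ", ")))
  list(errors = unique(errors), warnings = unique(warnings))
}

#' Simulate an SBML rate-rule model with a generic ODE integrator
#'
#' A small, model-agnostic SBML interpreter: the document's species and
#' rate-ruled parameters form the state vector, assignment rules are
#' evaluated in document order at every derivative call, and the system is
#' integrated with `deSolve`. It knows nothing about this package's native
#' model structure and therefore serves as an independent cross-check of
#' the exported document.
#'
#' @param document SBML as a string, file path or `xml2::xml_document`.
#' @param times Numeric vector of output times, h.
#' @param method `deSolve` integration method (default `"lsoda"`).
#' @return A data.frame with column `t` followed by one column per state
#'   variable.
#' @examples
#' doc <- export_sbml(sbml_model_spec())
#' head(simulate_sbml(doc, times = seq(0, 1, 0.1)))
#' @export
simulate_sbml <- function(document, times, method = "lsoda") {
  p <- parse_sbml(document)
  rep <- validate_sbml(document)
  if (length(rep$errors))
    stop("simulate_sbml: document fails consistency checks: ",
         paste(rep$errors, collapse = "; "))
  state_ids <- names(p$rate_rules)
  y0 <- c(p$species, p$variables)[state_ids]
  if (anyNA(y0)) stop("simulate_sbml: missing initial value for ",
                      paste(state_ids[is.na(y0)], collapse = ", "))
  consts <- c(p$parameters, p$compartments)
  asn <- p$assignment_rules
  rr <- p$rate_rules

  deriv <- function(t, y, parms) {
    env <- list2env(as.list(consts))
    for (nm in state_ids) assign(nm, y[[nm]], envir = env)
    for (nm in names(asn)) assign(nm, eval(asn[[nm]], env), envir = env)
    list(vapply(state_ids, function(nm) eval(rr[[nm]], env), numeric(1L)))
  }
  sol <- deSolve::ode(y = stats::setNames(as.numeric(y0), state_ids),
                      times = times, func = deriv, parms = NULL,
                      method = method)
  out <- as.data.frame(sol)
  names(out)[1L] <- "t"
  out
}
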