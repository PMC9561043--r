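# Declarative FHIR R4 structural shape subset.
#
# Resource shapes (kind: resource) are checked for every subject typed with
# their `type` IRI and additionally require the fhir:nodeRole fhir:treeRoot
# marker. Node shapes (kind: node) constrain nested element nodes reached
# through constraints. Primitive shapes (kind: primitive) require exactly
# one fhir:value arc carrying the declared XSD datatype; String doubles as
# the catch-all rule for underspecified primitive-string nodes.
# Constraints are closed-world per listed path; unlisted arcs are permitted.

prefixes:
  fhir: "http://hl7.org/fhir/"
  xsd: "http://www.w3.org/2001/XMLSchema#"

shapes:

  # --- primitive datatype shapes -------------------------------------------
  String:   {kind: primitive, datatype: "xsd:string"}
  Code:     {kind: primitive, datatype: "xsd:string"}
  Date:     {kind: primitive, datatype: "xsd:date"}
  DateTime: {kind: primitive, datatype: "xsd:dateTime"}
  Decimal:  {kind: primitive, datatype: "xsd:decimal"}
  Boolean:  {kind: primitive, datatype: "xsd:boolean"}

  # --- datatype node shapes ------------------------------------------------
  IdentifierNode:
    kind: node
    constraints:
      - {path: "fhir:Identifier.system", max: 1, shape: String}
      - {path: "fhir:Identifier.value", max: 1, shape: String}
  AddressNode:
    kind: node
    constraints:
      - {path: "fhir:Address.line", shape: String}
      - {path: "fhir:Address.city", max: 1, shape: String}
      - {path: "fhir:Address.state", max: 1, shape: String}
      - {path: "fhir:Address.postalCode", max: 1, shape: String}
  HumanNameNode:
    kind: node
    constraints:
      - {path: "fhir:HumanName.text", max: 1, shape: String}
  ReferenceNode:
    kind: node
    constraints:
      - {path: "fhir:Reference.reference", max: 1, shape: String}
      - {path: "fhir:link", max: 1, value: iri}
  PeriodNode:
    kind: node
    constraints:
      - {path: "fhir:Period.start", max: 1, shape: DateTime}
      - {path: "fhir:Period.end", max: 1, shape: DateTime}
  QuantityNode:
    kind: node
    constraints:
      - {path: "fhir:Quantity.value", max: 1, shape: Decimal}
      - {path: "fhir:Quantity.unit", max: 1, shape: String}
      - {path: "fhir:Quantity.system", max: 1, shape: String}
      - {path: "fhir:Quantity.code", max: 1, shape: String}
  CodingNode:
    kind: node
    constraints:
      - {path: "fhir:Coding.system", max: 1, shape: String}
      - {path: "fhir:Coding.code", max: 1, shape: Code}
      - {path: "fhir:Coding.display", max: 1, shape: String}
  CodeableConceptNode:
    kind: node
    constraints:
      - {path: "fhir:CodeableConcept.coding", shape: CodingNode}
      - {path: "fhir:CodeableConcept.text", max: 1, shape: String}
  ConceptMapGroup:
    kind: node
    constraints:
      - {path: "fhir:ConceptMap.group.element", min: 1, shape: ConceptMapElement}
  ConceptMapElement:
    kind: node
    constraints:
      - {path: "fhir:ConceptMap.group.element.code", max: 1, shape: Code}
      - {path: "fhir:ConceptMap.group.element.target", shape: ConceptMapTarget}
  ConceptMapTarget:
    kind: node
    constraints:
      - {path: "fhir:ConceptMap.group.element.target.code", max: 1, shape: Code}
      - {path: "fhir:ConceptMap.group.element.target.equivalence", max: 1, shape: Code}

  # --- resource shapes -----------------------------------------------------
  Patient:
    kind: resource
    type: "fhir:Patient"
    constraints:
      - {path: "fhir:Resource.id", min: 1, max: 1, shape: String}
      - {path: "fhir:Patient.identifier", shape: IdentifierNode}
      - {path: "fhir:Patient.active", max: 1, shape: Boolean}
      - {path: "fhir:Patient.gender", max: 1, shape: Code}
      - {path: "fhir:Patient.birthDate", max: 1, shape: Date}
      - {path: "fhir:Patient.address", shape: AddressNode}
      - {path: "fhir:Patient.generalPractitioner", shape: ReferenceNode}
  Encounter:
    kind: resource
    type: "fhir:Encounter"
    constraints:
      - {path: "fhir:Resource.id", min: 1, max: 1, shape: String}
      - {path: "fhir:Encounter.status", min: 1, max: 1, shape: Code}
      - {path: "fhir:Encounter.class", max: 1, shape: CodingNode}
      - {path: "fhir:Encounter.subject", min: 1, max: 1, shape: ReferenceNode}
      - {path: "fhir:Encounter.period", max: 1, shape: PeriodNode}
  Condition:
    kind: resource
    type: "fhir:Condition"
    constraints:
      - {path: "fhir:Resource.id", min: 1, max: 1, shape: String}
      - {path: "fhir:Condition.verificationStatus", max: 1, shape: CodeableConceptNode}
      - {path: "fhir:Condition.code", max: 1, shape: CodeableConceptNode}
      - {path: "fhir:Condition.subject", min: 1, max: 1, shape: ReferenceNode}
      - {path: "fhir:Condition.encounter", max: 1, shape: ReferenceNode}
      - {path: "fhir:Condition.onsetDateTime", max: 1, shape: DateTime}
  MedicationStatement:
    kind: resource
    type: "fhir:MedicationStatement"
    constraints:
      - {path: "fhir:Resource.id", min: 1, max: 1, shape: String}
      - {path: "fhir:MedicationStatement.status", min: 1, max: 1, shape: Code}
      - {path: "fhir:MedicationStatement.medicationCodeableConcept", max: 1, shape: CodeableConceptNode}
      - {path: "fhir:MedicationStatement.subject", min: 1, max: 1, shape: ReferenceNode}
      - {path: "fhir:MedicationStatement.context", max: 1, shape: ReferenceNode}
      - {path: "fhir:MedicationStatement.effectivePeriod", max: 1, shape: PeriodNode}
  Observation:
    kind: resource
    type: "fhir:Observation"
    constraints:
      - {path: "fhir:Resource.id", min: 1, max: 1, shape: String}
      - {path: "fhir:Observation.status", min: 1, max: 1, shape: Code}
      - {path: "fhir:Observation.code", max: 1, shape: CodeableConceptNode}
      - {path: "fhir:Observation.subject", min: 1, max: 1, shape: ReferenceNode}
      - {path: "fhir:Observation.encounter", max: 1, shape: ReferenceNode}
      - {path: "fhir:Observation.effectiveDateTime", max: 1, shape: DateTime}
      - {path: "fhir:Observation.valueQuantity", max: 1, shape: QuantityNode}
  Procedure:
    kind: resource
    type: "fhir:Procedure"
    constraints:
      - {path: "fhir:Resource.id", min: 1, max: 1, shape: String}
      - {path: "fhir:Procedure.status", min: 1, max: 1, shape: Code}
      - {path: "fhir:Procedure.code", max: 1, shape: CodeableConceptNode}
      - {path: "fhir:Procedure.subject", min: 1, max: 1, shape: ReferenceNode}
      - {path: "fhir:Procedure.encounter", max: 1, shape: ReferenceNode}
      - {path: "fhir:Procedure.performedDateTime", max: 1, shape: DateTime}
  Practitioner:
    kind: resource
    type: "fhir:Practitioner"
    constraints:
      - {path: "fhir:Resource.id", min: 1, max: 1, shape: String}
      - {path: "fhir:Practitioner.name", shape: HumanNameNode}
      - {path: "fhir:Practitioner.identifier", shape: IdentifierNode}
  Location:
    kind: resource
    type: "fhir:Location"
    constraints:
      - {path: "fhir:Resource.id", min: 1, max: 1, shape: String}
      - {path: "fhir:Location.address", max: 1, shape: AddressNode}
  CodeableConcept:
    kind: resource
    type: "fhir:CodeableConcept"
    constraints:
      - {path: "fhir:CodeableConcept.coding", shape: CodingNode}
      - {path: "fhir:CodeableConcept.text", max: 1, shape: String}
  Coding:
    kind: resource
    type: "fhir:Coding"
    constraints:
      - {path: "fhir:Coding.system", max: 1, shape: String}
      - {path: "fhir:Coding.code", max: 1, shape: Code}
      - {path: "fhir:Coding.display", max: 1, shape: String}
  ConceptMap:
    kind: resource
    type: "fhir:ConceptMap"
    constraints:
      - {path: "fhir:ConceptMap.group", min: 1, shape: ConceptMapGroup}
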