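@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix cso: <http://example.org/cso#> .
@prefix marl: <http://www.gsi.upm.es/ontologies/marl/ns#> .
@prefix OGMS: <http://purl.obolibrary.org/obo/ogms#> .
@prefix ex: <http://example.org/pekb/> .

# Merged Clinical Sentiment Ontology schema.
# Layer (a): clinical diagnosis concepts (OGMS reuse + cso additions).
OGMS:disease a rdfs:Class .
OGMS:diagnosis a rdfs:Class .
OGMS:therapeuticProcedure a rdfs:Class .
cso:Problem a rdfs:Class .
cso:Complication a rdfs:Class .
cso:Therapy a rdfs:Class .

# Layer (b): Marl opinion vocabulary.
marl:SentimentAnalysis a rdfs:Class .
marl:Opinion a rdfs:Class .
marl:SourceText a rdfs:Class .
marl:DescribedObject a rdfs:Class .
marl:DescribedObjectFeature a rdfs:Class .

# Layer (c): application layer.
cso:AnalysisResult a rdfs:Class .
cso:AnalyzedExperience a rdfs:Class .
cso:AnalyzedExperienceAspect a rdfs:Class .
cso:ClinicalConditionSet a rdfs:Class .
cso:ClinicalOpinionSet a rdfs:Class .
cso:ClinicalConditionSet rdfs:subClassOf cso:AnalysisResult .
cso:ClinicalOpinionSet rdfs:subClassOf cso:AnalysisResult .

# Object/data properties named in the ontology diagram.
cso:hasConditions a rdf:Property .
cso:hasOpinionSet a rdf:Property .
cso:hasCondition a rdf:Property .
cso:hasProcedure a rdf:Property .
marl:hasPolarity a rdf:Property .
marl:describesObject a rdf:Property .
marl:hasOpinion a rdf:Property .

# Artifact extensions: preference vectors, decisions and provenance are
# needed by the inference engine but are not drawn in the ontology diagram.
cso:containsOpinion a rdf:Property .
cso:caseId a rdf:Property .
cso:opinionWord a rdf:Property .
cso:docId a rdf:Property .
cso:sentenceIndex a rdf:Property .
cso:hasPreferenceAttribute a rdf:Property .
cso:attributeName a rdf:Property .
cso:attributeIndex a rdf:Property .
cso:vasValue a rdf:Property .
cso:priorityRank a rdf:Property .
cso:hasDecision a rdf:Property .
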