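{
  "systems": [
    {
      "name": "SNOMED CT",
      "uri_or_oid": "http://snomed.info/sct"
    },
    {
      "name": "LOINC",
      "uri_or_oid": "http://loinc.org"
    },
    {
      "name": "HGVS",
      "uri_or_oid": "http://varnomen.hgvs.org"
    },
    {
      "name": "ICD-10-GM",
      "uri_or_oid": "http://fhir.de/CodeSystem/bfarm/icd-10-gm"
    },
    {
      "name": "Alpha-ID",
      "uri_or_oid": "http://fhir.de/CodeSystem/bfarm/alpha-id"
    },
    {
      "name": "Orphanet",
      "uri_or_oid": "http://www.orpha.net"
    },
    {
      "name": "EBM",
      "uri_or_oid": "http://fhir.de/CodeSystem/kbv/ebm"
    },
    {
      "name": "ISCN",
      "uri_or_oid": "urn:oid:2.16.840.1.113883.6.335"
    },
    {
      "name": "v3.RoleCode",
      "uri_or_oid": "http://terminology.hl7.org/CodeSystem/v3-RoleCode"
    },
    {
      "name": "HGNC",
      "uri_or_oid": "http://www.genenames.org"
    },
    {
      "name": "FHIR risk-probability",
      "uri_or_oid": "http://terminology.hl7.org/CodeSystem/risk-probability"
    },
    {
      "name": "UCUM",
      "uri_or_oid": "http://unitsofmeasure.org"
    },
    {
      "name": "RefSeq",
      "uri_or_oid": "http://www.ncbi.nlm.nih.gov/refseq"
    },
    {
      "name": "MolGen local codes",
      "uri_or_oid": "https://example.org/fhir/molgen/CodeSystem/local"
    }
  ],
  "value_sets": [
    {
      "vs_id": "vs-condition-code",
      "description": "Condition coding slice for family member history and testing reasons: SNOMED CT, ICD-10-GM, Alpha-ID or Orphanet.",
      "systems": [
        "http://snomed.info/sct",
        "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
        "http://fhir.de/CodeSystem/bfarm/alpha-id",
        "http://www.orpha.net"
      ],
      "members": null
    },
    {
      "vs_id": "vs-family-member-snomed",
      "description": "SNOMED CT FamilyMember value set plus lineage and degree qualifier concepts. Codes beyond first/second degree concepts are synthetic placeholders (replaceable data).",
      "systems": [
        "http://snomed.info/sct"
      ],
      "members": null
    },
    {
      "vs_id": "vs-family-member-v3",
      "description": "v3.RoleCode family member role codes.",
      "systems": [
        "http://terminology.hl7.org/CodeSystem/v3-RoleCode"
      ],
      "members": null
    },
    {
      "vs_id": "vs-family-member-any",
      "description": "Union binding for FamilyMemberHistory.relationship: SNOMED CT FamilyMember or v3.RoleCode.",
      "systems": [
        "http://snomed.info/sct",
        "http://terminology.hl7.org/CodeSystem/v3-RoleCode"
      ],
      "members": null
    },
    {
      "vs_id": "vs-qualitative-risk",
      "description": "Qualitative risk levels for RiskAssessment.prediction.qualitativeRisk.",
      "systems": [
        "http://terminology.hl7.org/CodeSystem/risk-probability"
      ],
      "members": [
        {
          "system": "http://terminology.hl7.org/CodeSystem/risk-probability",
          "code": "negligible",
          "display": "Negligible likelihood"
        },
        {
          "system": "http://terminology.hl7.org/CodeSystem/risk-probability",
          "code": "low",
          "display": "Low likelihood"
        },
        {
          "system": "http://terminology.hl7.org/CodeSystem/risk-probability",
          "code": "moderate",
          "display": "Moderate likelihood"
        },
        {
          "system": "http://terminology.hl7.org/CodeSystem/risk-probability",
          "code": "high",
          "display": "High likelihood"
        },
        {
          "system": "http://terminology.hl7.org/CodeSystem/risk-probability",
          "code": "certain",
          "display": "Certain"
        }
      ]
    },
    {
      "vs_id": "vs-variant-origin",
      "description": "Genomic source class (variant origin) LOINC answers.",
      "systems": [
        "http://loinc.org"
      ],
      "members": [
        {
          "system": "http://loinc.org",
          "code": "LA6684-0",
          "display": "Somatic"
        },
        {
          "system": "http://loinc.org",
          "code": "LA6683-2",
          "display": "Germline"
        },
        {
          "system": "http://loinc.org",
          "code": "LA18194-3",
          "display": "Unknown genomic source class"
        }
      ]
    },
    {
      "vs_id": "vs-clinical-significance",
      "description": "Clinical significance LOINC answers.",
      "systems": [
        "http://loinc.org"
      ],
      "members": [
        {
          "system": "http://loinc.org",
          "code": "LA6668-3",
          "display": "Pathogenic"
        },
        {
          "system": "http://loinc.org",
          "code": "LA26332-9",
          "display": "Likely pathogenic"
        },
        {
          "system": "http://loinc.org",
          "code": "LA26333-7",
          "display": "Uncertain significance"
        },
        {
          "system": "http://loinc.org",
          "code": "LA26334-5",
          "display": "Likely benign"
        },
        {
          "system": "http://loinc.org",
          "code": "LA6675-8",
          "display": "Benign"
        }
      ]
    },
    {
      "vs_id": "vs-allelic-state",
      "description": "Allelic state LOINC answers.",
      "systems": [
        "http://loinc.org"
      ],
      "members": [
        {
          "system": "http://loinc.org",
          "code": "LA6705-3",
          "display": "Homozygous"
        },
        {
          "system": "http://loinc.org",
          "code": "LA6706-1",
          "display": "Heterozygous"
        },
        {
          "system": "http://loinc.org",
          "code": "LA6707-9",
          "display": "Hemizygous"
        }
      ]
    },
    {
      "vs_id": "vs-msi",
      "description": "Microsatellite instability status answers.",
      "systems": [
        "http://loinc.org"
      ],
      "members": [
        {
          "system": "http://loinc.org",
          "code": "LA14122-8",
          "display": "Stable"
        },
        {
          "system": "http://loinc.org",
          "code": "LA14123-6",
          "display": "Unstable low"
        },
        {
          "system": "http://loinc.org",
          "code": "LA14124-4",
          "display": "Unstable high"
        }
      ]
    },
    {
      "vs_id": "vs-specimen-type",
      "description": "Specimen type, SNOMED CT coded.",
      "systems": [
        "http://snomed.info/sct"
      ],
      "members": null
    }
  ]
}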