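{
  "reference_set": {
    "n_screened": 2102,
    "n_relevant": 431,
    "n_irrelevant": 1671,
    "note": "hand-screened reference set the published performance figures were measured on; the set itself is not deposited"
  },
  "filters": [
    {
      "name": "paramedic_sensitivity",
      "syntax": "ovid",
      "text": "Ambulances.sh OR Emergency Medical Technicians.sh OR Air Ambulances.sh OR emergency medical services.sh OR paramedic*.tw OR ems.tw OR emt.tw OR prehospital.tw OR pre-hospital.tw OR first responder*.tw OR emergency medical technicians.tw OR emergency services.tw OR Ambulance*.tw OR HEMS.tw OR field triage.tw OR out-of-hospital.tw",
      "reported_performance": {"sensitivity": 0.984, "specificity": 0.743, "nnr": 2.00},
      "note": "sensitivity-maximising paramedic filter (broad; for researchers); running-text NNR printed as 2"
    },
    {
      "name": "paramedic_specificity",
      "syntax": "ovid",
      "text": "Ambulances.sh OR Emergency Medical Technicians.sh OR Air Ambulances.sh OR paramedic*.tw OR ems.tw OR emt.tw OR prehospital.tw OR pre-hospital.tw OR first responder*.tw OR emergency medical technicians.tw OR emergency services.tw OR Ambulance*.tw OR HEMS.tw OR field triage.tw",
      "reported_performance": {"sensitivity": 0.947, "specificity": 0.883, "nnr": 1.48},
      "note": "specificity-maximising paramedic filter (narrow; for clinicians)"
    },
    {
      "name": "prehospital",
      "syntax": "ovid",
      "text": null,
      "reported_performance": {"sensitivity": 0.974, "specificity": 0.654, "nnr": 2.44},
      "note": "pre-existing prehospital filter evaluated on the same reference set; its query string is published elsewhere and is not packaged"
    }
  ]
}
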