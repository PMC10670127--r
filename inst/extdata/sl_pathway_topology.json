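{"nodes":[{"id":"SM_PM","name":"sphingomyelin","compartment":"plasma membrane","fluorescent":true,"type":"metabolite"},{"id":"CER_PM","name":"ceramide","compartment":"plasma membrane","fluorescent":true,"type":"metabolite"},{"id":"SO_PM","name":"sphingosine","compartment":"plasma membrane","fluorescent":false,"type":"metabolite"},{"id":"S1P","name":"sphingosine 1-phosphate","compartment":"cytosol","fluorescent":false,"type":"metabolite"},{"id":"SM_LYS","name":"sphingomyelin","compartment":"lysosome","fluorescent":true,"type":"metabolite"},{"id":"CER_LYS","name":"ceramide","compartment":"lysosome","fluorescent":true,"type":"metabolite"},{"id":"SO_LYS","name":"sphingosine","compartment":"lysosome","fluorescent":false,"type":"metabolite"},{"id":"CER_ER","name":"ceramide (de novo)","compartment":"ER","fluorescent":true,"type":"metabolite"},{"id":"CER_GOLGIIN","name":"ceramide","compartment":"Golgi-in","fluorescent":true,"type":"metabolite"},{"id":"CER_GOLGIOUT","name":"ceramide","compartment":"Golgi-out","fluorescent":true,"type":"metabolite"},{"id":"GLU_CER","name":"glucosylceramide","compartment":"Golgi-out","fluorescent":true,"type":"metabolite"},{"id":"SM_GOLGI","name":"sphingomyelin","compartment":"Golgi-in","fluorescent":true,"type":"metabolite"},{"id":"SERPALM","name":"serine + palmitoyl-CoA","compartment":"ER","fluorescent":false,"type":"precursor"},{"id":"P","name":"phagophore","compartment":"phagophore","fluorescent":false,"type":"stage"},{"id":"AP","name":"autophagosome","compartment":"autophagosome","fluorescent":true,"type":"stage"},{"id":"AL","name":"autophagolysosome","compartment":"autophagolysosome","fluorescent":true,"type":"stage"}],"edges":[{"id":"e_nsmase","substrate":"SM_PM","product":"CER_PM","enzyme":"neutral sphingomyelinase","type":"enzymatic","reconstructed":true},{"id":"e_ncdase","substrate":"CER_PM","product":"SO_PM","enzyme":"neutral/alkaline ceramidase","type":"enzymatic","reconstructed":false},{"id":"e_sphk","substrate":"SO_PM","product":"S1P","enzyme":"sphingosine kinase","type":"enzymatic","reconstructed":true},{"id":"e_asmase","substrate":"SM_LYS","product":"CER_LYS","enzyme":"acid sphingomyelinase","type":"enzymatic","reconstructed":true},{"id":"e_acdase","substrate":"CER_LYS","product":"SO_LYS","enzyme":"acid ceramidase","type":"enzymatic","reconstructed":false},{"id":"e_gcs","substrate":"CER_GOLGIOUT","product":"GLU_CER","enzyme":"glucosylceramide synthase","type":"enzymatic","reconstructed":false},{"id":"e_sms","substrate":"CER_GOLGIIN","product":"SM_GOLGI","enzyme":"sphingomyelin synthase","type":"enzymatic","reconstructed":true},{"id":"e_spt","substrate":"SERPALM","product":"CER_ER","enzyme":"serine palmitoyltransferase","type":"enzymatic","reconstructed":true},{"id":"t_cert","substrate":"CER_ER","product":"CER_GOLGIIN","enzyme":"ceramide transport (CERT)","type":"transport","reconstructed":true},{"id":"t_flip","substrate":"CER_GOLGIIN","product":"CER_GOLGIOUT","enzyme":"ceramide flip (Golgi)","type":"transport","reconstructed":true},{"id":"t_secr","substrate":"SM_GOLGI","product":"SM_PM","enzyme":"secretory transport","type":"transport","reconstructed":true},{"id":"s_phag","substrate":"SM_PM","product":"P","enzyme":"phagophore formation","type":"stage","reconstructed":false},{"id":"s_ap","substrate":"P","product":"AP","enzyme":"autophagosome formation","type":"stage","reconstructed":false},{"id":"s_al","substrate":"AP","product":"AL","enzyme":"autophagosome-lysosome fusion/acidification","type":"stage","reconstructed":false},{"id":"s_deliver","substrate":"AL","product":"SM_LYS","enzyme":"lysosomal delivery","type":"stage","reconstructed":true}],"inhibitors":[{"inhibitor":"SKI","edge_id":"e_sphk"},{"inhibitor":"PDMP","edge_id":"e_gcs"},{"inhibitor":"DES","edge_id":"e_asmase"},{"inhibitor":"DES","edge_id":"e_acdase"},{"inhibitor":"NCI","edge_id":"e_ncdase"},{"inhibitor":"D609","edge_id":"e_sms"},{"inhibitor":"ACI","edge_id":"e_acdase"},{"inhibitor":"GW","edge_id":"e_nsmase"},{"inhibitor":"MYR","edge_id":"e_spt"},{"inhibitor":"SPA","edge_id":"s_phag"},{"inhibitor":"HCQ","edge_id":"s_al"},{"inhibitor":"HCQ","edge_id":"e_acdase"}],"drugs":[]}
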