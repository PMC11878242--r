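name,parent,term,scope
biliary disorders,,,
biliary malignant tumours,biliary disorders,cholangiocarcinoma,narrow
biliary malignant tumours,biliary disorders,gallbladder cancer,narrow
biliary malignant tumours,biliary disorders,bile duct cancer metastatic,broad
biliary neoplasms benign (incl cysts and polyps),biliary disorders,gallbladder polyp,narrow
biliary neoplasms benign (incl cysts and polyps),biliary disorders,biliary cyst,narrow
biliary neoplasms benign (incl cysts and polyps),biliary disorders,bile duct adenoma,broad
biliary system related investigations signs and symptoms,biliary disorders,blood bilirubin increased,broad
biliary system related investigations signs and symptoms,biliary disorders,hepatic enzyme increased,broad
biliary system related investigations signs and symptoms,biliary disorders,jaundice,narrow
biliary system related investigations signs and symptoms,biliary disorders,biliary colic,narrow
biliary tract disorders,biliary disorders,bile duct obstruction,narrow
biliary tract disorders,biliary disorders,biliary dilatation,narrow
biliary tract disorders,biliary disorders,bile duct stenosis,broad
biliary tract disorders,biliary disorders,sphincter of oddi dysfunction,broad
biliary tumours of unspecified malignancy,biliary disorders,biliary neoplasm,narrow
congenital biliary disorders,biliary disorders,biliary atresia,narrow
congenital biliary disorders,biliary disorders,choledochal cyst congenital,broad
gallbladder related disorders,biliary disorders,cholecystitis,narrow
gallbladder related disorders,biliary disorders,cholecystitis acute,narrow
gallbladder related disorders,biliary disorders,gallbladder disorder,broad
gallbladder related disorders,biliary disorders,gallbladder enlargement,broad
gallstone related disorders,biliary disorders,cholelithiasis,narrow
gallstone related disorders,biliary disorders,bile duct stone,narrow
gallstone related disorders,biliary disorders,choledocholithiasis,narrow
infectious biliary disorders,biliary disorders,cholangitis,narrow
infectious biliary disorders,biliary disorders,cholangitis acute,narrow
infectious biliary disorders,biliary disorders,biliary sepsis,broad
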